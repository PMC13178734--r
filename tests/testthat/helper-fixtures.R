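# ---- small construction helpers -----------------------------------------

# entity set from surface/class vectors (spans are placeholders)
mk_set <- function(id, surfs, cls = "sym") {
  if (length(cls) == 1) cls <- rep(cls, length(surfs))
  m <- tibble::tibble(
    par_id = id, start = seq_along(surfs) * 10L,
    end = seq_along(surfs) * 10L + 1L, surface = surfs, class = cls
  )
  build_entity_set(id, m)
}

empty_mentions <- function() {
  tibble::tibble(
    par_id = character(), start = integer(), end = integer(),
    surface = character(), class = character()
  )
}

# paragraph graph assembled by hand (bypasses the builder)
mk_graph <- function(par_ids, doc_ids, intra = NULL, sim = NULL,
                     threshold = 0.5) {
  none <- tibble::tibble(from = character(), to = character(),
                         weight = numeric())
  structure(
    list(
      nodes = tibble::tibble(
        par_id = par_ids, doc_id = doc_ids,
        order_index = stats::ave(seq_along(par_ids), doc_ids,
                                 FUN = seq_along) - 1L
      ),
      intra_edges = if (is.null(intra)) none else intra,
      sim_edges = if (is.null(sim)) none else sim,
      threshold = threshold
    ),
    class = "med_paragraph_graph"
  )
}

edge_tbl <- function(from, to, weight) {
  tibble::tibble(from = from, to = to, weight = weight)
}

# one empty entity set per id
empty_sets <- function(ids) {
  purrr::map_dfr(ids, function(id) build_entity_set(id, empty_mentions()))
}

# ---- independent oracles -------------------------------------------------

# union-find partition of set ids connected through shared keys
# (independent of the package's tree algorithm)
uf_partition <- function(ids, key_list) {
  parent <- stats::setNames(seq_along(ids), ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[ra] <<- rb
  }
  key_owner <- list()
  for (n in seq_along(ids)) {
    for (k in key_list[[n]]) {
      if (is.null(key_owner[[k]])) key_owner[[k]] <- n
      else union_(key_owner[[k]], n)
    }
  }
  roots <- vapply(seq_along(ids), find, numeric(1))
  blocks <- split(ids, roots)
  blocks <- lapply(blocks, sort)
  unname(blocks[order(vapply(blocks, min, character(1)))])
}

# all set-partition membership vectors of n elements (canonical labels);
# cached per n since they are reused across random graphs
all_partitions_memo <- new.env(parent = emptyenv())
all_partitions <- function(n) {
  key <- as.character(n)
  if (!is.null(all_partitions_memo[[key]])) {
    return(all_partitions_memo[[key]])
  }
  grow <- function(mem) {
    if (length(mem) == n) return(list(mem))
    out <- list()
    for (b in seq_len(max(mem) + 1L)) {
      out <- c(out, grow(c(mem, b)))
    }
    out
  }
  res <- grow(c(1L))
  all_partitions_memo[[key]] <- res
  res
}

# brute-force minimum cut weight over all partitions obeying the size cap
brute_min_cut <- function(w, max_size) {
  n <- nrow(w)
  best <- Inf
  for (mem in all_partitions(n)) {
    if (max(table(mem)) > max_size) next
    cross <- outer(mem, mem, "!=") & upper.tri(w)
    cut <- sum(w[cross])
    if (cut < best) best <- cut
  }
  best
}

# random connected weighted graph as a hand-made paragraph graph
# (random spanning tree plus extra edges, uniform weights)
random_connected_graph <- function(n, seed, extra = n) {
  set.seed(seed)
  ids <- sprintf("v%02d", seq_len(n))
  from <- integer(0); to <- integer(0)
  for (i in 2:n) {
    from <- c(from, sample.int(i - 1L, 1))
    to <- c(to, i)
  }
  for (e in seq_len(extra)) {
    p <- sample.int(n, 2)
    from <- c(from, min(p)); to <- c(to, max(p))
  }
  keep <- !duplicated(paste(from, to)) & from != to
  from <- from[keep]; to <- to[keep]
  w <- round(stats::runif(length(from), 0.05, 1), 3)
  mk_graph(ids, rep("doc", n),
           sim = edge_tbl(ids[from], ids[to], w))
}

# membership vector (named by par id) from a constellation tibble
membership_of <- function(constellations) {
  m <- constellation_membership(constellations)
  stats::setNames(m$constellation, m$par_id)
}

# total cut weight of a constellation partition on a hand-made graph
graph_cut_weight <- function(graph, constellations) {
  mem <- membership_of(constellations)
  edges <- dplyr::bind_rows(
    graph$intra_edges[, c("from", "to", "weight")],
    graph$sim_edges[, c("from", "to", "weight")]
  )
  sum(edges$weight[mem[edges$from] != mem[edges$to]])
}
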