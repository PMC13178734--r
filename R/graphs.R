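#' Build the document similarity graph (space view)
#'
#' Nodes are documents sized by character length; edges link every document
#' pair whose cosine similarity strictly exceeds `theta_doc`. Connected
#' components under the threshold are the document clusters ("nebulae"),
#' labeled by their modal topic when a topic model is supplied.
#'
#' @param corpus A [med_corpus()].
#' @param vectors Document embedding matrix (rownames = doc ids), e.g. from
#'   [embed_documents()].
#' @param theta_doc Similarity threshold in `[0, 1]`; strict.
#' @param topic_model Optional `med_topic_model` for topic labels.
#' @return A `med_document_graph`: list with `nodes` (tibble `doc_id`,
#'   `size`, `topic`, `cluster`, `cluster_topic`), `edges` (tibble `from`,
#'   `to`, `weight`) and `threshold`.
#' @export
build_document_graph <- function(corpus, vectors, theta_doc = 0.5,
                                 topic_model = NULL) {
  stopifnot(inherits(corpus, "med_corpus"), theta_doc >= 0, theta_doc <= 1)
  docs <- corpus$documents
  miss <- setdiff(docs$doc_id, rownames(vectors))
  if (length(miss) > 0) {
    stop("missing vector for document(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  ids <- sort(docs$doc_id)
  m <- vectors[ids, , drop = FALSE]
  edges <- tibble::tibble(from = character(), to = character(),
                          weight = numeric())
  if (length(ids) > 1) {
    s <- cosine_matrix(m)
    idx <- which(upper.tri(s) & s > theta_doc, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      edges <- tibble::tibble(
        from = ids[idx[, 1]], to = ids[idx[, 2]],
        weight = s[idx]
      ) |> dplyr::arrange(.data$from, .data$to)
    }
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = ids)
  )
  comp <- igraph::components(g)$membership
  topic <- rep(NA_integer_, length(ids))
  if (!is.null(topic_model)) {
    topic <- topic_model$assignments$topic[
      match(ids, topic_model$assignments$doc_id)
    ]
  }
  nodes <- tibble::tibble(
    doc_id = ids,
    size = docs$char_length[match(ids, docs$doc_id)],
    topic = topic,
    cluster = as.integer(comp[ids])
  )
  modal <- nodes |>
    dplyr::filter(!is.na(.data$topic)) |>
    dplyr::count(.data$cluster, .data$topic) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  nodes$cluster_topic <- modal$topic[match(nodes$cluster, modal$cluster)]
  structure(
    list(nodes = nodes, edges = edges, threshold = theta_doc),
    class = "med_document_graph"
  )
}

#' @export
print.med_document_graph <- function(x, ...) {
  cat(sprintf(
    "<med_document_graph> %d documents, %d edges (threshold %.3g), %d clusters\n",
    nrow(x$nodes), nrow(x$edges), x$threshold,
    length(unique(x$nodes$cluster))
  ))
  invisible(x)
}

#' Build the paragraph graph (star map substrate)
#'
#' Vertices are the paragraphs of the selected documents. Intra-document
#' edges `E_d` chain order-adjacent paragraphs of one document; similarity
#' edges `E_s` link paragraphs of *different* documents whose cosine
#' similarity strictly exceeds `theta`. Cross-document candidates are
#' restricted to document pairs linked in `doc_graph`; if the selection has
#' no document edges at all (or `doc_graph` is `NULL`), every cross-document
#' pair is a candidate so the view still functions.
#'
#' @param corpus A [med_corpus()].
#' @param selected_docs Character vector of selected doc ids.
#' @param vectors Paragraph embedding matrix (rownames = par ids).
#' @param doc_graph Optional `med_document_graph` gating E_s candidates.
#' @param theta Similarity threshold in `[0, 1]`; strict.
#' @return A `med_paragraph_graph`: list with `nodes` (tibble `par_id`,
#'   `doc_id`, `order_index`), `intra_edges` (`from`, `to`, `weight` = 1),
#'   `sim_edges` (`from`, `to`, `weight`) and `threshold`.
#' @export
build_paragraph_graph <- function(corpus, selected_docs = NULL, vectors,
                                  doc_graph = NULL, theta = 0.5) {
  stopifnot(inherits(corpus, "med_corpus"), theta >= 0, theta <= 1)
  if (is.null(selected_docs)) selected_docs <- corpus$documents$doc_id
  absent <- setdiff(selected_docs, corpus$documents$doc_id)
  if (length(absent) > 0) {
    stop("selected document(s) not in corpus: ",
      paste(absent, collapse = ", "),
      call. = FALSE
    )
  }
  pars <- corpus$paragraphs[corpus$paragraphs$doc_id %in% selected_docs, ]
  pars <- pars[order(pars$doc_id, pars$order_index), ]
  miss <- setdiff(pars$par_id, rownames(vectors))
  if (length(miss) > 0) {
    stop("missing vector for paragraph(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  nodes <- tibble::tibble(
    par_id = pars$par_id, doc_id = pars$doc_id,
    order_index = pars$order_index
  )
  intra <- tibble::tibble(from = character(), to = character(),
                          weight = numeric())
  if (nrow(nodes) > 0) {
    chains <- nodes |>
      dplyr::group_by(.data$doc_id) |>
      dplyr::arrange(.data$order_index, .by_group = TRUE) |>
      dplyr::summarise(
        from = list(.data$par_id[-dplyr::n()]),
        to = list(.data$par_id[-1]),
        .groups = "drop"
      )
    f <- unlist(chains$from)
    t <- unlist(chains$to)
    if (is.null(f)) f <- character()
    if (is.null(t)) t <- character()
    intra <- tibble::tibble(from = f, to = t, weight = rep(1, length(f)))
  }

  # candidate document pairs for E_s
  sel <- sort(unique(selected_docs))
  if (!is.null(doc_graph)) {
    de <- doc_graph$edges
    de <- de[de$from %in% sel & de$to %in% sel, c("from", "to")]
    linked <- de
  } else {
    linked <- tibble::tibble(from = character(), to = character())
  }
  if (nrow(linked) == 0 && length(sel) > 1) {
    cmb <- utils::combn(sel, 2)
    linked <- tibble::tibble(from = cmb[1, ], to = cmb[2, ])
  }
  sim_edges <- tibble::tibble(from = character(), to = character(),
                              weight = numeric())
  if (nrow(linked) > 0 && nrow(nodes) > 1) {
    m <- vectors[nodes$par_id, , drop = FALSE]
    s <- cosine_matrix(m)
    doc_of <- nodes$doc_id
    pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    allowed <- pair_key(linked$from, linked$to)
    idx <- which(upper.tri(s), arr.ind = TRUE)
    keep <- doc_of[idx[, 1]] != doc_of[idx[, 2]] &
      pair_key(doc_of[idx[, 1]], doc_of[idx[, 2]]) %in% allowed &
      s[idx] > theta
    idx <- idx[keep, , drop = FALSE]
    if (nrow(idx) > 0) {
      sim_edges <- tibble::tibble(
        from = nodes$par_id[idx[, 1]], to = nodes$par_id[idx[, 2]],
        weight = s[idx]
      ) |> dplyr::arrange(.data$from, .data$to)
    }
  }
  structure(
    list(nodes = nodes, intra_edges = intra, sim_edges = sim_edges,
         threshold = theta),
    class = "med_paragraph_graph"
  )
}

#' @export
print.med_paragraph_graph <- function(x, ...) {
  cat(sprintf(
    "<med_paragraph_graph> %d paragraphs, %d intra edges, %d similarity edges (threshold %.3g)\n",
    nrow(x$nodes), nrow(x$intra_edges), nrow(x$sim_edges), x$threshold
  ))
  invisible(x)
}

# weighted adjacency matrix over the given node ordering
paragraph_adjacency <- function(graph, ids = NULL) {
  if (is.null(ids)) ids <- sort(graph$nodes$par_id)
  n <- length(ids)
  w <- matrix(0, n, n, dimnames = list(ids, ids))
  add <- function(e) {
    if (nrow(e) == 0) return()
    i <- match(e$from, ids)
    j <- match(e$to, ids)
    ok <- !is.na(i) & !is.na(j)
    for (r in which(ok)) {
      w[i[r], j[r]] <<- w[i[r], j[r]] + e$weight[r]
      w[j[r], i[r]] <<- w[i[r], j[r]]
    }
  }
  add(graph$intra_edges)
  add(graph$sim_edges)
  w
}

# cut weight of a block membership vector against adjacency w
partition_cut_weight <- function(w, membership) {
  cross <- outer(membership, membership, "!=")
  sum(w[cross & upper.tri(w)])
}

# exact minimum-cut partition with block-size cap, by pruned enumeration
# (canonical block order: node 1 in block 1, node i opens at most one new
# block). Suitable for components of up to ~10 nodes.
exact_partition <- function(w, max_size) {
  n <- nrow(w)
  best_cut <- Inf
  best_mem <- rep(1L, n)
  mem <- integer(n)
  sizes <- integer(n)
  recurse <- function(i, nblocks, cut) {
    if (cut >= best_cut) return()
    if (i > n) {
      best_cut <<- cut
      best_mem <<- mem[seq_len(n)]
      return()
    }
    for (b in seq_len(min(nblocks + 1L, n))) {
      if (b <= nblocks && sizes[b] >= max_size) next
      inc <- 0
      if (i > 1) {
        prev <- seq_len(i - 1L)
        inc <- sum(w[i, prev][mem[prev] != b])
      }
      mem[i] <<- b
      sizes[b] <<- sizes[b] + 1L
      recurse(i + 1L, max(nblocks, b), cut + inc)
      sizes[b] <<- sizes[b] - 1L
      if (b > nblocks) break
    }
  }
  recurse(1L, 0L, 0)
  list(membership = best_mem, cut = best_cut)
}

# one Kernighan-Lin refinement of a fixed-size bipartition (logical side)
kl_refine <- function(w, side) {
  n <- length(side)
  repeat {
    locked <- rep(FALSE, n)
    cur <- side
    gains <- numeric(0)
    swaps <- list()
    d <- vapply(seq_len(n), function(i) {
      sum(w[i, cur != cur[i]]) - sum(w[i, cur == cur[i] & seq_len(n) != i])
    }, numeric(1))
    for (step in seq_len(floor(min(sum(side), sum(!side))))) {
      a_idx <- which(cur & !locked)
      b_idx <- which(!cur & !locked)
      if (length(a_idx) == 0 || length(b_idx) == 0) break
      best <- c(NA, NA, -Inf)
      for (a in a_idx) {
        g <- d[a] + d[b_idx] - 2 * w[a, b_idx]
        bi <- which.max(g)
        if (g[bi] > best[3]) best <- c(a, b_idx[bi], g[bi])
      }
      a <- best[1]; b <- best[2]
      locked[c(a, b)] <- TRUE
      gains <- c(gains, best[3])
      swaps[[length(swaps) + 1L]] <- c(a, b)
      # update D values as if a and b swapped sides
      for (i in which(!locked)) {
        if (cur[i] == cur[a]) d[i] <- d[i] + 2 * w[i, a] - 2 * w[i, b]
        else d[i] <- d[i] + 2 * w[i, b] - 2 * w[i, a]
      }
      tmp <- cur[a]; cur[a] <- cur[b]; cur[b] <- tmp
    }
    if (length(gains) == 0) break
    cum <- cumsum(gains)
    kbest <- which.max(cum)
    if (cum[kbest] <= 1e-12) break
    for (s in seq_len(kbest)) {
      ab <- swaps[[s]]
      tmp <- side[ab[1]]; side[ab[1]] <- side[ab[2]]; side[ab[2]] <- tmp
    }
  }
  side
}

# recursive KL bisection for components larger than the exact threshold
kl_partition <- function(w, max_size, seed, restarts = 5L) {
  n <- nrow(w)
  if (n <= max_size) return(rep(1L, n))
  n1 <- ceiling(n / 2)
  best_side <- NULL
  best_cut <- Inf
  for (r in seq_len(restarts)) {
    side <- with_rng_seed(seed + 7919L * r, {
      s <- rep(FALSE, n)
      s[sample.int(n, n1)] <- TRUE
      s
    })
    side <- kl_refine(w, side)
    cut <- sum(w[side, !side, drop = FALSE])
    if (cut < best_cut - 1e-12) {
      best_cut <- cut
      best_side <- side
    }
  }
  left <- kl_partition(w[best_side, best_side, drop = FALSE], max_size,
                       seed + 1L, restarts)
  right <- kl_partition(w[!best_side, !best_side, drop = FALSE], max_size,
                        seed + 2L, restarts)
  mem <- integer(n)
  mem[best_side] <- left
  mem[!best_side] <- right + max(left)
  mem
}

#' Partition the paragraph graph into constellations
#'
#' Splits the paragraph graph into blocks of at most `max_size` vertices
#' while minimizing the total weight of cut edges (`E_d` edges weigh 1,
#' `E_s` edges weigh their similarity). Connected components are computed
#' first; a component exceeding the cap is split — exactly (pruned
#' enumeration) when it has at most `exact_threshold` vertices, otherwise by
#' recursive bisection with Kernighan-Lin refinement from seeded restarts.
#' Deterministic given the seed; ties resolve toward the smallest node id.
#'
#' @param graph A `med_paragraph_graph`.
#' @param max_size Maximum constellation size (default 10).
#' @param seed Integer seed for the refinement restarts.
#' @param exact_threshold Components up to this size are split optimally
#'   (default 9).
#' @return Tibble with one row per constellation: `id`, `members`
#'   (list-column of par ids), `star_count`.
#' @export
partition_paragraph_graph <- function(graph, max_size = 10L, seed = 1L,
                                      exact_threshold = 9L) {
  stopifnot(inherits(graph, "med_paragraph_graph"), max_size >= 1)
  ids <- sort(graph$nodes$par_id)
  if (length(ids) == 0) {
    return(tibble::tibble(
      id = integer(), members = list(), star_count = integer()
    ))
  }
  edges <- dplyr::bind_rows(
    graph$intra_edges[, c("from", "to")],
    graph$sim_edges[, c("from", "to")]
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership[ids]
  blocks <- list()
  for (cid in sort(unique(comp))) {
    members <- ids[comp == cid]
    if (length(members) <= max_size) {
      blocks[[length(blocks) + 1L]] <- members
      next
    }
    w <- paragraph_adjacency(graph, members)
    mem <- if (length(members) <= exact_threshold) {
      exact_partition(w, max_size)$membership
    } else {
      kl_partition(w, max_size, seed)
    }
    for (b in sort(unique(mem))) {
      blocks[[length(blocks) + 1L]] <- members[mem == b]
    }
  }
  # deterministic constellation order: by smallest member id
  ord <- order(vapply(blocks, min, character(1)))
  blocks <- blocks[ord]
  tibble::tibble(
    id = seq_along(blocks),
    members = lapply(blocks, sort),
    star_count = vapply(blocks, length, integer(1))
  )
}

#' Membership vector of a constellation partition
#'
#' @param constellations Output of [partition_paragraph_graph()].
#' @return Tibble `par_id`, `constellation`.
#' @export
constellation_membership <- function(constellations) {
  tidyr::unnest(
    constellations[, c("id", "members")],
    cols = "members"
  ) |>
    dplyr::rename(constellation = "id", par_id = "members") |>
    dplyr::select("par_id", "constellation")
}
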