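# entity keys are encoded "class:surface" (class codes are fixed-width)
encode_keys <- function(keys) {
  if (nrow(keys) == 0) return(character())
  sort(paste(keys$class, keys$surface, sep = ":"))
}

decode_key_class <- function(key) substr(key, 1, 3)
decode_key_surface <- function(key) substring(key, 5)

#' Create an empty association tree
#'
#' The association tree groups medical entity sets (MESs) that share
#' entities into common branches under a single root: two MESs end up in the
#' same root-level branch exactly when they are connected through shared
#' entity keys (transitively). Shared entities are promoted to branch-level
#' ME nodes when held by at least two member MESs; each MES node keeps its
#' constituent MEs as collapsed leaf children for progressive disclosure.
#'
#' @return An empty `med_association_tree`.
#' @seealso [insert_entity_set()], [build_tree()], [branch_partition()]
#' @export
association_tree <- function() {
  structure(
    list(
      mes_keys = list(),   # mes_id -> sorted character keys
      root_mes = character(),
      branches = list()    # each a character vector of member mes ids
    ),
    class = "med_association_tree"
  )
}

#' @export
print.med_association_tree <- function(x, ...) {
  cat(sprintf(
    "<med_association_tree> %d entity sets, %d branches, %d singletons\n",
    length(x$mes_keys), length(x$branches), length(x$root_mes)
  ))
  invisible(x)
}

#' Insert one entity set into the association tree
#'
#' The new set's keys are checked against every existing member; all
#' branches (and root-level MES nodes) containing an intersecting member are
#' merged with the new node into a single branch under the root — the merge
#' realizes their common ancestor. With no intersection anywhere the node
#' attaches directly to the root.
#'
#' @param tree A `med_association_tree`.
#' @param mes A one-row entity-set tibble (from [build_entity_set()]) or a
#'   row of [build_entity_sets()] output.
#' @return The updated tree.
#' @export
insert_entity_set <- function(tree, mes) {
  stopifnot(inherits(tree, "med_association_tree"))
  id <- mes$mes_id[1]
  if (id %in% names(tree$mes_keys)) {
    stop("duplicate entity-set id: ", id, call. = FALSE)
  }
  keys <- encode_keys(mes$keys[[1]])
  intersects <- function(other_id) {
    length(intersect(tree$mes_keys[[other_id]], keys)) > 0
  }
  hit_branches <- which(vapply(
    tree$branches,
    function(members) any(vapply(members, intersects, logical(1))),
    logical(1)
  ))
  hit_root <- tree$root_mes[vapply(tree$root_mes, intersects, logical(1))]
  tree$mes_keys[[id]] <- keys
  if (length(hit_branches) == 0 && length(hit_root) == 0) {
    tree$root_mes <- c(tree$root_mes, id)
    return(tree)
  }
  merged <- c(unlist(tree$branches[hit_branches]), hit_root, id)
  tree$branches[hit_branches] <- NULL
  tree$root_mes <- setdiff(tree$root_mes, hit_root)
  tree$branches[[length(tree$branches) + 1L]] <- sort(unname(merged))
  tree
}

#' Build an association tree from entity sets
#'
#' Folds [insert_entity_set()] over the rows of `sets` in order; further
#' sets can be inserted incrementally afterwards. The resulting branch
#' partition does not depend on the insertion order.
#'
#' @param sets Entity-set tibble from [build_entity_sets()].
#' @return A `med_association_tree`.
#' @export
build_tree <- function(sets) {
  if (nrow(sets) == 0) return(association_tree())
  if (anyDuplicated(sets$mes_id)) {
    stop("duplicate entity-set ids", call. = FALSE)
  }
  tree <- association_tree()
  for (i in seq_len(nrow(sets))) {
    tree <- insert_entity_set(tree, sets[i, ])
  }
  tree
}

#' Partition of MES ids induced by the tree's root children
#'
#' One block per root child: a branch yields the set of its member MESs, a
#' root-level MES a singleton. Blocks are sorted and ordered by their
#' smallest member so the result is deterministic.
#'
#' @param tree A `med_association_tree`.
#' @return List of character vectors (possibly empty).
#' @export
branch_partition <- function(tree) {
  stopifnot(inherits(tree, "med_association_tree"))
  blocks <- c(tree$branches, as.list(tree$root_mes))
  blocks <- lapply(blocks, sort)
  if (length(blocks) == 0) return(list())
  blocks[order(vapply(blocks, min, character(1)))]
}

# keys shared by >= 2 members of a branch, sorted
branch_shared_keys <- function(tree, members) {
  all_keys <- unlist(tree$mes_keys[members], use.names = FALSE)
  tab <- table(all_keys)
  sort(names(tab)[tab >= 2])
}

#' Color of an entity set
#'
#' Component-wise average of the class palette colors weighted by
#' `num_ij / num_i` — the weighted mixture of the set's constituent entity
#' types.
#'
#' @param mes A one-row entity-set tibble (`total > 0`).
#' @param palette Palette tibble (`class`, `r`, `g`, `b`), default
#'   [default_class_palette()].
#' @return Numeric RGB triple in `[0, 1]`.
#' @export
mes_color <- function(mes, palette = default_class_palette()) {
  keys <- mes$keys[[1]]
  if (nrow(keys) == 0) stop("entity set is empty", call. = FALSE)
  counts <- dplyr::count(keys, .data$class)
  w <- counts$n / sum(counts$n)
  rows <- match(counts$class, palette$class)
  c(
    r = sum(w * palette$r[rows]),
    g = sum(w * palette$g[rows]),
    b = sum(w * palette$b[rows])
  )
}

# color of a bare key vector (used for tree export)
keys_color <- function(keys, palette = default_class_palette()) {
  cls <- decode_key_class(keys)
  tab <- table(cls)
  w <- as.numeric(tab) / sum(tab)
  rows <- match(names(tab), palette$class)
  c(
    r = sum(w * palette$r[rows]),
    g = sum(w * palette$g[rows]),
    b = sum(w * palette$b[rows])
  )
}

rgb_hex <- function(col) {
  grDevices::rgb(col[1], col[2], col[3])
}

#' Render the association tree as nested nodes
#'
#' Produces the export structure of the radial dendrogram: a `ROOT` whose
#' children are `BRANCH` nodes (members sharing entities) and singleton
#' `MES_NODE`s. Branch children list the promoted shared `ME_NODE`s first
#' (keys held by >= 2 members), then the member MES nodes; every MES node
#' carries its constituent ME leaves as `collapsed` children so renderers
#' can disclose them progressively. Node colors mix the class palette by
#' entity-type weight.
#'
#' @param tree A `med_association_tree`.
#' @param palette Class palette tibble.
#' @return Nested list `{kind, payload, color, collapsed, children}`.
#' @export
as_tree_nodes <- function(tree, palette = default_class_palette()) {
  stopifnot(inherits(tree, "med_association_tree"))
  me_node <- function(key, collapsed) {
    cls <- decode_key_class(key)
    row <- match(cls, palette$class)
    list(
      kind = "ME_NODE",
      payload = list(surface = decode_key_surface(key), class = cls),
      color = rgb_hex(c(palette$r[row], palette$g[row], palette$b[row])),
      collapsed = collapsed,
      children = list()
    )
  }
  mes_node <- function(id) {
    keys <- tree$mes_keys[[id]]
    col <- if (length(keys) > 0) rgb_hex(keys_color(keys, palette)) else
      "#808080"
    list(
      kind = "MES_NODE",
      payload = list(mes_id = id),
      color = col,
      collapsed = FALSE,
      children = lapply(keys, me_node, collapsed = TRUE)
    )
  }
  branch_node <- function(members) {
    members <- sort(members)
    shared <- branch_shared_keys(tree, members)
    keys_all <- unlist(tree$mes_keys[members], use.names = FALSE)
    list(
      kind = "BRANCH",
      payload = NULL,
      color = if (length(keys_all)) rgb_hex(keys_color(keys_all, palette))
        else "#808080",
      collapsed = FALSE,
      children = c(
        lapply(shared, me_node, collapsed = FALSE),
        lapply(members, mes_node)
      )
    )
  }
  blocks <- branch_partition(tree)
  children <- lapply(blocks, function(b) {
    if (length(b) == 1) mes_node(b) else branch_node(b)
  })
  list(
    kind = "ROOT", payload = NULL, color = "#000000", collapsed = FALSE,
    children = children
  )
}
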