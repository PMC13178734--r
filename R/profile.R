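#' Focus targets for the sectional view
#'
#' A focus is either a single entity (normalized surface + class) or a whole
#' entity set; the sectional profile summarizes everything co-occurring with
#' it.
#'
#' @param surface Entity surface form (normalized internally).
#' @param class Entity class code.
#' @return A `med_focus` object.
#' @export
focus_entity <- function(surface, class) {
  assert_entity_class(class)
  structure(
    list(kind = "entity", surface = normalize_surface(surface),
         class = class, mes_id = NULL),
    class = "med_focus"
  )
}

#' @rdname focus_entity
#' @param mes_id Entity-set (paragraph) identifier.
#' @export
focus_mes <- function(mes_id) {
  structure(
    list(kind = "mes", surface = NULL, class = NULL, mes_id = mes_id),
    class = "med_focus"
  )
}

set_has_key <- function(keys, surface, class) {
  any(keys$surface == surface & keys$class == class)
}

#' Entity sets co-occurring with a focus
#'
#' For an entity focus: every MES containing the key, ordered by id. For an
#' MES focus: the focal set first, then every other set sharing at least one
#' key with it, ordered by id.
#'
#' @param focus A `med_focus`.
#' @param sets Entity-set tibble from [build_entity_sets()].
#' @return Subset of `sets` rows in profile order.
#' @export
co_occurring_sets <- function(focus, sets) {
  stopifnot(inherits(focus, "med_focus"))
  if (focus$kind == "entity") {
    hit <- vapply(
      sets$keys, set_has_key, logical(1),
      surface = focus$surface, class = focus$class
    )
    out <- sets[hit, ]
    return(out[order(out$mes_id), ])
  }
  at <- match(focus$mes_id, sets$mes_id)
  if (is.na(at)) {
    stop("no entity set with id ", focus$mes_id, call. = FALSE)
  }
  focal_keys <- encode_keys(sets$keys[[at]])
  share <- vapply(sets$keys, function(k) {
    length(intersect(encode_keys(k), focal_keys)) > 0
  }, logical(1))
  share[at] <- FALSE
  others <- sets[share, ]
  others <- others[order(others$mes_id), ]
  dplyr::bind_rows(sets[at, ], others)
}

# greedy nearest-neighbor seriation over class-count profiles
order_axes <- function(counts_wide) {
  n <- nrow(counts_wide)
  if (n <= 1) return(seq_len(n))
  m <- as.matrix(counts_wide[, -1])
  totals <- rowSums(m)
  sims <- cosine_matrix(m)
  ids <- counts_wide[[1]]
  start <- order(-totals, ids)[1]
  visited <- start
  while (length(visited) < n) {
    rest <- setdiff(seq_len(n), visited)
    s <- sims[visited[length(visited)], rest]
    pick <- rest[order(-s, ids[rest])[1]]
    visited <- c(visited, pick)
  }
  visited
}

#' Build a focused sectional profile
#'
#' One radial axis per co-occurring entity set with per-class heights
#' `N_ik * h_t` (`N_ik` = distinct entities of class k in set i); the donut
#' is the class distribution aggregated over all axes, normalized to sum to
#' one. Axes are ordered by greedy nearest-neighbor seriation on the cosine
#' similarity of their class-count profiles (starting from the largest
#' axis, ties by id) so areas of the same class tend to connect across
#' adjacent axes.
#'
#' @param focus A `med_focus`.
#' @param sets Entity-set tibble from [build_entity_sets()].
#' @param h_t Height unit (> 0), default 1.
#' @return A `med_sectional_profile`: list with `focus`, `focal_class`
#'   (entity focus only), `axes` (long tibble `axis`, `mes_id`, `par_id`,
#'   `doc_id`, `class`, `n`, `height`), `donut` (tibble `class`,
#'   `fraction`) and `h_t`.
#' @export
build_profile <- function(focus, sets, h_t = 1) {
  if (!is.numeric(h_t) || h_t <= 0) {
    stop("h_t must be a positive number", call. = FALSE)
  }
  co <- co_occurring_sets(focus, sets)
  focal_class <- if (focus$kind == "entity") focus$class else NULL
  if (nrow(co) == 0) {
    return(structure(
      list(
        focus = focus, focal_class = focal_class,
        axes = tibble::tibble(
          axis = integer(), mes_id = character(), par_id = character(),
          doc_id = character(), class = character(), n = integer(),
          height = numeric()
        ),
        donut = tibble::tibble(class = character(), fraction = numeric()),
        h_t = h_t
      ),
      class = "med_sectional_profile"
    ))
  }
  counts <- mes_class_counts(co)
  wide <- tidyr::pivot_wider(counts, names_from = "class",
                             values_from = "n")
  wide <- wide[match(co$mes_id, wide$mes_id),
               c("mes_id", ENTITY_CLASS_CODES)]
  ord <- if (focus$kind == "mes") {
    # focal axis stays first; remaining axes seriated
    c(1L, if (nrow(wide) > 1) 1L + order_axes(wide[-1, ]) else integer())
  } else {
    order_axes(wide)
  }
  axis_ids <- wide$mes_id[ord]
  axes <- counts |>
    dplyr::filter(.data$mes_id %in% axis_ids) |>
    dplyr::mutate(
      axis = match(.data$mes_id, axis_ids),
      par_id = co$par_id[match(.data$mes_id, co$mes_id)],
      doc_id = co$doc_id[match(.data$mes_id, co$mes_id)],
      height = .data$n * h_t
    ) |>
    dplyr::arrange(.data$axis, match(.data$class, ENTITY_CLASS_CODES)) |>
    dplyr::select("axis", "mes_id", "par_id", "doc_id", "class", "n",
                  "height")
  agg <- axes |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  total <- sum(agg$n)
  donut <- if (total > 0) {
    tibble::tibble(
      class = ENTITY_CLASS_CODES,
      fraction = agg$n[match(ENTITY_CLASS_CODES, agg$class)] / total
    )
  } else {
    tibble::tibble(class = character(), fraction = numeric())
  }
  structure(
    list(focus = focus, focal_class = focal_class, axes = axes,
         donut = donut, h_t = h_t),
    class = "med_sectional_profile"
  )
}

#' @export
print.med_sectional_profile <- function(x, ...) {
  cat(sprintf(
    "<med_sectional_profile> %s focus, %d axes\n",
    x$focus$kind, length(unique(x$axes$mes_id))
  ))
  invisible(x)
}

#' Retrieve the provenance document card for an axis
#'
#' Returns the full parent document of the axis's paragraph with the set's
#' mentions mapped to document coordinates as highlight spans. With a class
#' filter only that class's spans are kept and the earliest one becomes the
#' scroll anchor.
#'
#' @param axis An axis identifier: an `mes_id`, or a row subset of a
#'   profile's `axes` tibble (its first `mes_id` is used).
#' @param corpus The [med_corpus()] the sets were built from.
#' @param sets Entity-set tibble.
#' @param class_filter Optional entity class code.
#' @return A `med_document_card`: list with `doc_id`, `text`, `spans`
#'   (tibble `start`, `end`, `class`, document coordinates), `anchor`
#'   (offset or `NA`) and `active_class_filter`.
#' @export
provenance_lookup <- function(axis, corpus, sets, class_filter = NULL) {
  stopifnot(inherits(corpus, "med_corpus"))
  mes_id <- if (is.data.frame(axis)) axis$mes_id[1] else axis
  at <- match(mes_id, sets$mes_id)
  if (is.na(at)) stop("no entity set with id ", mes_id, call. = FALSE)
  par_at <- match(sets$par_id[at], corpus$paragraphs$par_id)
  if (is.na(par_at)) {
    stop("paragraph ", sets$par_id[at], " not in corpus", call. = FALSE)
  }
  par <- corpus$paragraphs[par_at, ]
  doc_at <- match(par$doc_id, corpus$documents$doc_id)
  doc <- corpus$documents[doc_at, ]
  mentions <- sets$mentions[[at]]
  spans <- if (nrow(mentions) > 0) {
    tibble::tibble(
      start = mentions$start + par$start,
      end = mentions$end + par$start,
      class = mentions$class
    )
  } else {
    tibble::tibble(start = integer(), end = integer(), class = character())
  }
  if (!is.null(class_filter)) {
    assert_entity_class(class_filter)
    spans <- spans[spans$class == class_filter, ]
  }
  spans <- spans[order(spans$start), ]
  structure(
    list(
      doc_id = doc$doc_id,
      text = doc$text,
      spans = spans,
      anchor = if (nrow(spans) > 0) spans$start[1] else NA_integer_,
      active_class_filter = class_filter
    ),
    class = "med_document_card"
  )
}

#' @export
print.med_document_card <- function(x, ...) {
  cat(sprintf(
    "<med_document_card> %s, %d highlight spans%s\n",
    x$doc_id, nrow(x$spans),
    if (is.null(x$active_class_filter)) "" else
      sprintf(" (filter: %s)", x$active_class_filter)
  ))
  invisible(x)
}
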