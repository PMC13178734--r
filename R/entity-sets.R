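#' Build the medical entity set (MES) of one paragraph
#'
#' An MES holds the *distinct* typed entities of a paragraph: mentions are
#' deduplicated by entity key (normalized surface + class). Per-class counts
#' `num_ij` therefore count distinct keys, not raw mentions; the raw mentions
#' are retained for highlighting and provenance.
#'
#' @param paragraph_id Paragraph identifier; becomes the MES id.
#' @param mentions Mention tibble (`start`, `end`, `surface`, `class`, and a
#'   `par_id` column when produced by [extract_corpus_entities()]). All
#'   mentions must belong to `paragraph_id`.
#' @param doc_id Optional parent document id carried for provenance.
#' @return One-row tibble with columns `mes_id`, `par_id`, `doc_id`, `total`
#'   (`num_i`), `keys` (list-column tibble `surface`, `class`) and
#'   `mentions` (list-column of the input mentions).
#' @export
build_entity_set <- function(paragraph_id, mentions, doc_id = NA_character_) {
  mentions <- tibble::as_tibble(mentions)
  if ("par_id" %in% names(mentions) && nrow(mentions) > 0) {
    if (any(mentions$par_id != paragraph_id)) {
      stop("mention from a different paragraph than ", paragraph_id,
        call. = FALSE
      )
    }
    if ("doc_id" %in% names(mentions) && is.na(doc_id)) {
      doc_id <- mentions$doc_id[1]
    }
  }
  if (nrow(mentions) > 0) {
    assert_entity_class(mentions$class)
    keys <- tibble::tibble(
      surface = normalize_surface(mentions$surface),
      class = mentions$class
    ) |>
      dplyr::distinct() |>
      dplyr::arrange(.data$class, .data$surface)
  } else {
    keys <- tibble::tibble(surface = character(), class = character())
  }
  tibble::tibble(
    mes_id = paragraph_id,
    par_id = paragraph_id,
    doc_id = doc_id,
    total = nrow(keys),
    keys = list(keys),
    mentions = list(mentions)
  )
}

#' Build entity sets for every paragraph of a corpus
#'
#' One MES per paragraph, including paragraphs with no mentions (empty set,
#' `total = 0`).
#'
#' @param corpus A [med_corpus()].
#' @param mentions Mentions from [extract_corpus_entities()].
#' @return Tibble of entity sets, one row per paragraph (see
#'   [build_entity_set()]).
#' @export
build_entity_sets <- function(corpus, mentions) {
  stopifnot(inherits(corpus, "med_corpus"))
  pars <- corpus$paragraphs
  split_m <- split(mentions, factor(mentions$par_id, levels = pars$par_id))
  purrr::map_dfr(seq_len(nrow(pars)), function(i) {
    build_entity_set(pars$par_id[i], split_m[[i]], doc_id = pars$doc_id[i])
  })
}

#' Per-class distinct-entity counts of entity sets
#'
#' The counts `num_ij` (distinct entity keys of class j in set i) and totals
#' `num_i` used by the pole springs, node colors and sectional profiles.
#'
#' @param sets Entity-set tibble from [build_entity_sets()].
#' @param complete Return a row for every (set, class) pair, zero-filled
#'   (default `TRUE`).
#' @return Long tibble `mes_id`, `class`, `n`.
#' @export
mes_class_counts <- function(sets, complete = TRUE) {
  counts <- purrr::map2_dfr(sets$mes_id, sets$keys, function(id, k) {
    if (nrow(k) == 0) return(NULL)
    dplyr::count(k, .data$class) |>
      dplyr::mutate(mes_id = id, .before = 1)
  })
  if (nrow(counts) == 0) {
    counts <- tibble::tibble(
      mes_id = character(), class = character(), n = integer()
    )
  }
  if (!complete) return(counts)
  tidyr::complete(
    counts,
    mes_id = sets$mes_id,
    class = ENTITY_CLASS_CODES,
    fill = list(n = 0L)
  ) |>
    dplyr::arrange(
      match(.data$mes_id, sets$mes_id),
      match(.data$class, ENTITY_CLASS_CODES)
    )
}
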