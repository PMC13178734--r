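#' Normalize an entity surface form
#'
#' Case-folds and collapses internal whitespace. Two mentions whose
#' normalized surface and class agree are the same entity key; keys are the
#' unit of co-occurrence throughout the package.
#'
#' @param x Character vector of surface forms.
#' @return Normalized character vector.
#' @export
normalize_surface <- function(x) {
  stringr::str_squish(stringr::str_to_lower(x))
}

#' Compile a gazetteer for entity matching
#'
#' @param entries Tibble (or data frame) with columns `surface` and `class`.
#'   Duplicate (surface, class) pairs are deduplicated; the same surface
#'   listed under two classes is an error.
#' @return A `med_gazetteer` object supporting leftmost-longest matching.
#' @export
compile_gazetteer <- function(entries) {
  entries <- tibble::as_tibble(entries)
  stopifnot(all(c("surface", "class") %in% names(entries)))
  if (nrow(entries) == 0) stop("gazetteer is empty", call. = FALSE)
  assert_entity_class(entries$class, "gazetteer class")
  entries$surface <- normalize_surface(entries$surface)
  if (any(!nzchar(entries$surface))) {
    stop("gazetteer surface empty after normalization", call. = FALSE)
  }
  entries <- dplyr::distinct(entries, .data$surface, .data$class)
  conf <- entries |>
    dplyr::count(.data$surface) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conf) > 0) {
    stop("conflicting classes for surface(s): ",
      paste(conf$surface, collapse = ", "),
      call. = FALSE
    )
  }
  # alternation ordered longest-first so the regex engine returns the
  # longest candidate at each position; scanning itself is leftmost-first
  ord <- order(-nchar(entries$surface), entries$surface)
  entries <- entries[ord, ]
  esc <- stringr::str_replace_all(
    entries$surface, "([.^$|()\\[\\]{}*+?\\\\])", "\\\\\\1"
  )
  esc <- stringr::str_replace_all(esc, stringr::fixed(" "), "\\s+")
  pattern <- paste0("(?:", paste(esc, collapse = "|"), ")")
  lookup <- stats::setNames(entries$class, entries$surface)
  structure(
    list(entries = entries, pattern = pattern, lookup = lookup),
    class = "med_gazetteer"
  )
}

#' @export
print.med_gazetteer <- function(x, ...) {
  cat(sprintf("<med_gazetteer> %d entries\n", nrow(x$entries)))
  invisible(x)
}

#' Read a gazetteer from a TSV file
#'
#' Format: `surface<TAB>class_code`, UTF-8, one entry per line; lines
#' starting with `#` are comments.
#'
#' @param path Path to the TSV file.
#' @return A compiled `med_gazetteer`.
#' @export
read_gazetteer <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- stringr::str_split_fixed(lines, "\t", 2)
  if (any(!nzchar(parts[, 2]))) {
    stop("gazetteer line without a tab-separated class code", call. = FALSE)
  }
  compile_gazetteer(tibble::tibble(
    surface = parts[, 1], class = trimws(parts[, 2])
  ))
}

#' Extract entity mentions from text
#'
#' Case-insensitive, leftmost-longest, non-overlapping substring matching of
#' the gazetteer surfaces (character-based; no tokenization, so it works for
#' Chinese and English alike). Offsets are 0-based half-open code points into
#' `text`.
#'
#' @param text A single string.
#' @param gazetteer A compiled `med_gazetteer`.
#' @return Tibble with columns `start`, `end`, `surface` (the matched slice
#'   of `text`), `class`, sorted by `start`.
#' @export
#' @examples
#' gz <- compile_gazetteer(tibble::tibble(
#'   surface = c("candidiasis", "oral candidiasis"), class = "dis"
#' ))
#' extract_entities("Oral candidiasis was noted.", gz)
extract_entities <- function(text, gazetteer) {
  stopifnot(inherits(gazetteer, "med_gazetteer"), length(text) == 1)
  empty <- tibble::tibble(
    start = integer(), end = integer(),
    surface = character(), class = character()
  )
  if (is.na(text) || nchar(text) == 0) return(empty)
  loc <- stringr::str_locate_all(
    text, stringr::regex(gazetteer$pattern, ignore_case = TRUE)
  )[[1]]
  if (nrow(loc) == 0) return(empty)
  surface <- substr(rep(text, nrow(loc)), loc[, 1], loc[, 2])
  tibble::tibble(
    start = as.integer(loc[, 1] - 1L),
    end = as.integer(loc[, 2]),
    surface = surface,
    class = unname(gazetteer$lookup[normalize_surface(surface)])
  )
}

#' Extract mentions for every paragraph of a corpus
#'
#' The extractor is pluggable: any deterministic function mapping paragraph
#' text to a mention tibble (`start`, `end`, `surface`, `class`, with valid
#' non-overlapping spans) can be supplied. By default the gazetteer matcher
#' is used; if the corpus carries pre-annotated mentions those are returned
#' verbatim instead (`use_annotations = TRUE`).
#'
#' @param corpus A [med_corpus()] whose documents have paragraphs.
#' @param gazetteer A compiled `med_gazetteer` (required unless annotations
#'   are used or a custom `extractor` is given).
#' @param extractor Optional function `function(text) -> mention tibble`.
#' @param use_annotations Use the corpus's pre-annotated mentions when
#'   present (default `TRUE`).
#' @return Tibble of mentions: `par_id`, `doc_id`, `start`, `end`,
#'   `surface`, `class`.
#' @export
extract_corpus_entities <- function(corpus, gazetteer = NULL,
                                    extractor = NULL,
                                    use_annotations = TRUE) {
  stopifnot(inherits(corpus, "med_corpus"))
  pars <- corpus$paragraphs
  if (use_annotations && nrow(corpus$annotations) > 0) {
    a <- corpus$annotations
    a$surface <- slice_chars(
      pars$text[match(a$par_id, pars$par_id)], a$start, a$end
    )
    a$doc_id <- pars$doc_id[match(a$par_id, pars$par_id)]
    return(a[order(a$par_id, a$start),
             c("par_id", "doc_id", "start", "end", "surface", "class")])
  }
  if (is.null(extractor)) {
    if (is.null(gazetteer)) {
      stop("supply a gazetteer or a custom extractor", call. = FALSE)
    }
    extractor <- function(text) extract_entities(text, gazetteer)
  }
  out <- purrr::map_dfr(seq_len(nrow(pars)), function(i) {
    m <- extractor(pars$text[i])
    if (nrow(m) == 0) return(NULL)
    m$par_id <- pars$par_id[i]
    m$doc_id <- pars$doc_id[i]
    m
  })
  if (nrow(out) == 0) {
    return(tibble::tibble(
      par_id = character(), doc_id = character(), start = integer(),
      end = integer(), surface = character(), class = character()
    ))
  }
  out[order(out$par_id, out$start),
      c("par_id", "doc_id", "start", "end", "surface", "class")]
}
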