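#' Medical text corpora
#'
#' A corpus holds medical documents (MDs) and their ordered medical
#' paragraphs (MPs). Paragraph offsets are 0-based, half-open, counted in
#' Unicode code points, so `text` of a paragraph always equals the parent
#' document slice `[start, end)`.
#'
#' @param documents Tibble with columns `doc_id`, `title` (may be `NA`),
#'   `text`, `char_length`.
#' @param paragraphs Tibble with columns `par_id`, `doc_id`, `order_index`
#'   (0-based, contiguous per document), `text`, `start`, `end`.
#' @param annotations Optional tibble of pre-annotated entity mentions with
#'   columns `par_id`, `start`, `end`, `class` (paragraph-relative offsets).
#' @return An object of class `med_corpus`: a list with elements
#'   `documents`, `paragraphs` and `annotations`.
#' @seealso [read_corpus()], [write_corpus()], [segment_corpus()]
#' @export
med_corpus <- function(documents, paragraphs = NULL, annotations = NULL) {
  if (is.null(paragraphs)) {
    paragraphs <- tibble::tibble(
      par_id = character(), doc_id = character(), order_index = integer(),
      text = character(), start = integer(), end = integer()
    )
  }
  if (is.null(annotations)) {
    annotations <- tibble::tibble(
      par_id = character(), start = integer(), end = integer(),
      class = character()
    )
  }
  documents <- tibble::as_tibble(documents)
  if (!"title" %in% names(documents)) documents$title <- NA_character_
  if (!"char_length" %in% names(documents)) {
    documents$char_length <- nchar(documents$text, type = "chars")
  }
  documents <- documents[, c("doc_id", "title", "text", "char_length")]
  corpus <- structure(
    list(
      documents = documents,
      paragraphs = tibble::as_tibble(paragraphs),
      annotations = tibble::as_tibble(annotations)
    ),
    class = "med_corpus"
  )
  validate_corpus(corpus)
  corpus
}

#' @export
print.med_corpus <- function(x, ...) {
  cat(sprintf(
    "<med_corpus> %d documents, %d paragraphs, %d pre-annotated mentions\n",
    nrow(x$documents), nrow(x$paragraphs), nrow(x$annotations)
  ))
  invisible(x)
}

# code-point slice with 0-based half-open offsets
slice_chars <- function(text, start, end) {
  substring(text, start + 1L, end)
}

validate_corpus <- function(corpus) {
  docs <- corpus$documents
  pars <- corpus$paragraphs
  if (anyDuplicated(docs$doc_id)) {
    stop("duplicate document id: ",
      paste(unique(docs$doc_id[duplicated(docs$doc_id)]), collapse = ", "),
      call. = FALSE
    )
  }
  if (any(docs$char_length != nchar(docs$text, type = "chars"))) {
    stop("char_length inconsistent with text", call. = FALSE)
  }
  if (nrow(pars) == 0) return(invisible(corpus))
  if (anyDuplicated(pars$par_id)) {
    stop("duplicate paragraph id", call. = FALSE)
  }
  orphan <- setdiff(pars$doc_id, docs$doc_id)
  if (length(orphan) > 0) {
    stop("paragraph references unknown document: ",
      paste(orphan, collapse = ", "),
      call. = FALSE
    )
  }
  joined <- dplyr::left_join(
    pars, docs[, c("doc_id", "text", "char_length")],
    by = "doc_id", suffix = c("", ".doc")
  )
  bad <- joined$start < 0 | joined$start >= joined$end |
    joined$end > joined$char_length
  if (any(bad)) {
    stop("paragraph offsets out of bounds for paragraph ",
      paste(joined$par_id[bad], collapse = ", "),
      call. = FALSE
    )
  }
  slice <- slice_chars(joined$text.doc, joined$start, joined$end)
  if (any(slice != joined$text)) {
    stop("paragraph text does not equal the parent document slice",
      call. = FALSE
    )
  }
  ord_ok <- pars |>
    dplyr::group_by(.data$doc_id) |>
    dplyr::summarise(
      ok = identical(sort(.data$order_index), seq_along(.data$order_index) - 1L),
      .groups = "drop"
    )
  if (!all(ord_ok$ok)) {
    stop("order_index not contiguous from 0 within document(s): ",
      paste(ord_ok$doc_id[!ord_ok$ok], collapse = ", "),
      call. = FALSE
    )
  }
  invisible(corpus)
}

#' Read a corpus from a JSONL file
#'
#' One JSON object per line:
#' `{"id", "title"?, "text", "paragraphs"?: [{"id","start","end"}],
#' "entities"?: [{"pid","start","end","class"}]}`. Documents without
#' pre-split paragraphs get an empty paragraph list; call
#' [segment_corpus()] afterwards to segment them.
#'
#' @param path Path to a JSONL file.
#' @return A [med_corpus()].
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  docs <- vector("list", length(lines))
  pars <- list()
  anns <- list()
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) {
        stop(sprintf("malformed JSONL at line %d: %s", i, conditionMessage(e)),
          call. = FALSE
        )
      }
    )
    if (is.null(rec$id) || is.null(rec$text)) {
      stop(sprintf("malformed JSONL at line %d: missing 'id' or 'text'", i),
        call. = FALSE
      )
    }
    docs[[i]] <- tibble::tibble(
      doc_id = as.character(rec$id),
      title = if (is.null(rec$title)) NA_character_ else as.character(rec$title),
      text = as.character(rec$text)
    )
    if (!is.null(rec$paragraphs) && length(rec$paragraphs) > 0) {
      p <- purrr::map_dfr(rec$paragraphs, function(q) {
        tibble::tibble(
          par_id = as.character(q$id),
          start = as.integer(q$start), end = as.integer(q$end)
        )
      })
      p$doc_id <- as.character(rec$id)
      p$order_index <- seq_len(nrow(p)) - 1L
      p$text <- slice_chars(rec$text, p$start, p$end)
      pars[[length(pars) + 1L]] <- p
    }
    if (!is.null(rec$entities) && length(rec$entities) > 0) {
      a <- purrr::map_dfr(rec$entities, function(q) {
        tibble::tibble(
          par_id = as.character(q$pid),
          start = as.integer(q$start), end = as.integer(q$end),
          class = as.character(q$class)
        )
      })
      anns[[length(anns) + 1L]] <- a
    }
  }
  documents <- if (length(docs)) dplyr::bind_rows(docs) else
    tibble::tibble(doc_id = character(), title = character(), text = character())
  paragraphs <- if (length(pars)) {
    dplyr::bind_rows(pars)[, c("par_id", "doc_id", "order_index", "text",
                               "start", "end")]
  } else NULL
  annotations <- if (length(anns)) dplyr::bind_rows(anns) else NULL
  if (!is.null(annotations) && nrow(annotations) > 0) {
    assert_entity_class(annotations$class)
  }
  med_corpus(documents, paragraphs, annotations)
}

#' Write a corpus to a JSONL file
#'
#' Serialization is canonical: documents are sorted by id, keys appear in a
#' fixed order and integers are printed without decoration, so structurally
#' identical corpora always produce byte-identical files.
#'
#' @param corpus A [med_corpus()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "med_corpus"))
  docs <- corpus$documents[order(corpus$documents$doc_id), ]
  lines <- purrr::map_chr(seq_len(nrow(docs)), function(i) {
    d <- docs[i, ]
    rec <- list(id = d$doc_id)
    if (!is.na(d$title)) rec$title <- d$title
    rec$text <- d$text
    p <- corpus$paragraphs[corpus$paragraphs$doc_id == d$doc_id, ]
    if (nrow(p) > 0) {
      p <- p[order(p$order_index), ]
      rec$paragraphs <- purrr::pmap(
        list(p$par_id, p$start, p$end),
        function(id, s, e) list(id = id, start = s, end = e)
      )
      a <- corpus$annotations[corpus$annotations$par_id %in% p$par_id, ]
      if (nrow(a) > 0) {
        a <- a[order(match(a$par_id, p$par_id), a$start), ]
        rec$entities <- purrr::pmap(
          list(a$par_id, a$start, a$end, a$class),
          function(pid, s, e, cl) list(pid = pid, start = s, end = e, class = cl)
        )
      }
    }
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  })
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines) > 0) {
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' Segment text into paragraphs
#'
#' Splits on runs of one or more blank lines (consecutive blank lines
#' collapse into a single delimiter); with `mode = "line"` every newline is a
#' delimiter. Fragments whose stripped length is below `min_len` are merged
#' into the previous segment (the first fragment merges right). Offsets are
#' 0-based, half-open, in code points; concatenating the segment slices and
#' the delimiters between them reconstructs the input.
#'
#' @param text A single string.
#' @param min_len Minimum stripped segment length (code points), default 2.
#' @param mode `"blank_line"` (default) or `"line"`.
#' @return Tibble with columns `start`, `end`, one row per segment, in order.
#' @export
#' @examples
#' segment_document("Chief complaint: pain\n\nHistory: two weeks")
segment_document <- function(text, min_len = 2L, mode = c("blank_line", "line")) {
  stopifnot(length(text) == 1, min_len >= 1)
  mode <- match.arg(mode)
  empty <- tibble::tibble(start = integer(), end = integer())
  if (is.na(text) || nchar(text) == 0) return(empty)
  delim_re <- if (mode == "line") "\\n" else "\\n(?:[^\\S\\n]*\\n)+"
  locs <- stringr::str_locate_all(text, delim_re)[[1]]
  n <- nchar(text, type = "chars")
  bounds_start <- c(0L, as.integer(locs[, "end"]))
  bounds_end <- c(as.integer(locs[, "start"]) - 1L, n)
  segs <- tibble::tibble(start = bounds_start, end = bounds_end)
  stripped_len <- function(s, e) {
    nchar(trimws(slice_chars(text, s, e)), type = "chars")
  }
  segs$slen <- mapply(stripped_len, segs$start, segs$end)
  # drop leading fragments below min_len by merging them rightwards
  while (nrow(segs) > 1 && segs$slen[1] < min_len) {
    segs$start[2] <- segs$start[1]
    segs <- segs[-1, ]
    segs$slen[1] <- stripped_len(segs$start[1], segs$end[1])
  }
  # merge any later short fragment into its predecessor
  keep <- list(segs[1, ])
  if (nrow(segs) > 1) {
    for (i in 2:nrow(segs)) {
      if (segs$slen[i] < min_len) {
        last <- keep[[length(keep)]]
        last$end <- segs$end[i]
        last$slen <- stripped_len(last$start, last$end)
        keep[[length(keep)]] <- last
      } else {
        keep[[length(keep) + 1L]] <- segs[i, ]
      }
    }
  }
  segs <- dplyr::bind_rows(keep)
  if (nrow(segs) == 1 && segs$slen[1] == 0) return(empty)
  segs[, c("start", "end")]
}

#' Segment all unsegmented documents of a corpus
#'
#' Documents that already carry paragraphs (pre-split in the input) are left
#' untouched; all others are segmented with [segment_document()]. Generated
#' paragraph ids are `<doc_id>:p<order_index>`.
#'
#' @inheritParams write_corpus
#' @inheritParams segment_document
#' @return A new [med_corpus()] in which every document has paragraphs.
#' @export
segment_corpus <- function(corpus, min_len = 2L, mode = c("blank_line", "line")) {
  stopifnot(inherits(corpus, "med_corpus"))
  mode <- match.arg(mode)
  done <- unique(corpus$paragraphs$doc_id)
  todo <- corpus$documents[!corpus$documents$doc_id %in% done, ]
  if (nrow(todo) == 0) return(corpus)
  new_pars <- purrr::map_dfr(seq_len(nrow(todo)), function(i) {
    d <- todo[i, ]
    segs <- segment_document(d$text, min_len = min_len, mode = mode)
    if (nrow(segs) == 0) return(NULL)
    tibble::tibble(
      par_id = sprintf("%s:p%d", d$doc_id, seq_len(nrow(segs)) - 1L),
      doc_id = d$doc_id,
      order_index = seq_len(nrow(segs)) - 1L,
      text = slice_chars(d$text, segs$start, segs$end),
      start = segs$start, end = segs$end
    )
  })
  med_corpus(
    corpus$documents,
    dplyr::bind_rows(corpus$paragraphs, new_pars),
    corpus$annotations
  )
}
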