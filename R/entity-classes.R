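#' The nine medical entity classes
#'
#' Medical entities are typed with one of nine classes, following the Chinese
#' medical-entity annotation standard: disease (`dis`), clinical symptom
#' (`sym`), drug (`dru`), medical equipment (`equ`), medical procedure
#' (`pro`), body (`bod`), medical examination item (`ite`), microorganism
#' (`mic`) and department (`dep`). The order of the codes is fixed; the
#' ordinal (0-8) determines the angular position of each class pole on the
#' star map.
#'
#' @return A tibble with columns `code` (character), `ordinal` (integer 0-8)
#'   and `label` (human-readable class name).
#' @export
#' @examples
#' entity_classes()
entity_classes <- function() {
  tibble::tibble(
    code = c("dis", "sym", "dru", "equ", "pro", "bod", "ite", "mic", "dep"),
    ordinal = 0:8,
    label = c(
      "disease", "clinical symptom", "drug", "medical equipment",
      "medical procedure", "body", "examination item", "microorganism",
      "department"
    )
  )
}

#' @rdname entity_classes
#' @format NULL
#' @export
ENTITY_CLASS_CODES <- c(
  "dis", "sym", "dru", "equ", "pro", "bod", "ite", "mic", "dep"
)

is_entity_class <- function(x) x %in% ENTITY_CLASS_CODES

assert_entity_class <- function(x, what = "entity class") {
  bad <- setdiff(unique(x), ENTITY_CLASS_CODES)
  if (length(bad) > 0) {
    stop(sprintf(
      "invalid %s: %s (expected one of %s)",
      what, paste(bad, collapse = ", "),
      paste(ENTITY_CLASS_CODES, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(x)
}

#' Default categorical palette for the nine entity classes
#'
#' Colors are given as RGB triples in `[0, 1]`, one distinct color per class.
#' Mixed node colors (for entity sets) are computed as weighted averages of
#' these per-class colors with [mes_color()].
#'
#' @return A tibble with columns `class`, `r`, `g`, `b`.
#' @export
default_class_palette <- function() {
  # Okabe-Ito-like 9-color categorical palette, distinct and CVD-friendly.
  hex <- c(
    dis = "#E69F00", sym = "#56B4E9", dru = "#009E73",
    equ = "#F0E442", pro = "#0072B2", bod = "#D55E00",
    ite = "#CC79A7", mic = "#999999", dep = "#000000"
  )
  rgb <- grDevices::col2rgb(hex) / 255
  tibble::tibble(
    class = names(hex),
    r = rgb["red", ], g = rgb["green", ], b = rgb["blue", ]
  )
}
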