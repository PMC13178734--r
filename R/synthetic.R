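#' Configuration for the synthetic clinical-note generator
#'
#' @param n_diseases Number of diseases (>= 1).
#' @param docs_per_disease Documents generated per disease (>= 1).
#' @param sections_per_doc Paragraphs (sections) per document (>= 1); the
#'   five clinical sections (chief complaint, medical history, examination,
#'   diagnosis, treatment) are cycled.
#' @param entities_per_paragraph Mean number of planted entity mentions per
#'   paragraph (Poisson rate, min 1 planted per paragraph).
#' @param overlap_fraction Share of each disease's entity vocabulary drawn
#'   from a pool common to all diseases, in `[0, 1]`; 0 makes disease
#'   vocabularies fully disjoint.
#' @param pool_size Entity surfaces per class per disease.
#' @param dim Embedding dimension recorded for downstream steps.
#' @param seed Integer seed; all generator output is a pure function of the
#'   configuration.
#' @return A `med_synth_config` list.
#' @export
synth_config <- function(n_diseases = 4L, docs_per_disease = 5L,
                         sections_per_doc = 5L, entities_per_paragraph = 4,
                         overlap_fraction = 0, pool_size = 4L,
                         dim = 256L, seed = 1L) {
  if (n_diseases < 1 || docs_per_disease < 1 || sections_per_doc < 1 ||
      entities_per_paragraph < 1 || pool_size < 1) {
    stop("all counts and rates must be >= 1", call. = FALSE)
  }
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stop("overlap_fraction must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      n_diseases = as.integer(n_diseases),
      docs_per_disease = as.integer(docs_per_disease),
      sections_per_doc = as.integer(sections_per_doc),
      entities_per_paragraph = entities_per_paragraph,
      overlap_fraction = overlap_fraction,
      pool_size = as.integer(pool_size),
      dim = as.integer(dim),
      seed = as.integer(seed)
    ),
    class = "med_synth_config"
  )
}

# fixed-length pseudo-words: equal length means no surface can be a
# substring of another, so leftmost-longest extraction is exact
make_surfaces <- function(n, len = 8L) {
  made <- character(0)
  while (length(made) < n) {
    w <- paste(
      sample(letters, len * (n - length(made)), replace = TRUE),
      collapse = ""
    )
    w <- substring(w, seq(1, nchar(w), by = len),
                   seq(len, nchar(w), by = len))
    made <- unique(c(made, w))
  }
  made[seq_len(n)]
}

synth_sections <- function() {
  list(
    list(
      name = "chief_complaint",
      classes = c("sym", "bod"),
      open = "Chief complaint: the patient reports ",
      sep = ", ", close = " since last week."
    ),
    list(
      name = "medical_history",
      classes = c("dis", "pro", "dru"),
      open = "Medical history: prior records note ",
      sep = ", ", close = " over several years."
    ),
    list(
      name = "examination",
      classes = c("equ", "ite", "bod"),
      open = "Examination: assessment with ",
      sep = ", ", close = " was completed today."
    ),
    list(
      name = "diagnosis",
      classes = c("dis", "mic"),
      open = "Diagnosis: findings are consistent with ",
      sep = ", ", close = " on review."
    ),
    list(
      name = "treatment",
      classes = c("dru", "pro", "dep"),
      open = "Treatment: management included ",
      sep = ", ", close = " as advised."
    )
  )
}

#' Generate a synthetic multi-disease clinical corpus
#'
#' Emulates sectioned clinical notes: each document belongs to one disease
#' and cycles through chief complaint, medical history, examination,
#' diagnosis and treatment paragraphs whose sentences carry planted entity
#' mentions of the nine classes. Entity surfaces are fixed-length
#' pseudo-words unique per disease except for a configurable share drawn
#' from a common pool, so cross-disease vocabulary overlap (and therefore
#' cluster separability and cross-disease co-occurrence) is controlled
#' exactly. The emitted gazetteer covers exactly the planted surfaces and
#' the ground truth records document labels, every planted mention and the
#' co-occurrence components induced by shared planted keys.
#'
#' @param config A [synth_config()].
#' @return List with elements `corpus` ([med_corpus()] with pre-split
#'   paragraphs), `gazetteer` (tibble `surface`, `class`), `truth` (list:
#'   `doc_labels`, `planted_mentions`, `cooccurrence_components`, `roles`)
#'   and `config`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "med_synth_config"))
  sections <- synth_sections()
  with_rng_seed(config$seed, {
    ps <- config$pool_size
    n_common <- round(config$overlap_fraction * ps)
    # one flat draw of distinct surfaces: common pool + per-disease pools
    need <- 9 * (n_common + config$n_diseases * (ps - n_common))
    all_surf <- make_surfaces(need)
    cursor <- 0L
    take <- function(k) {
      out <- all_surf[cursor + seq_len(k)]
      cursor <<- cursor + k
      out
    }
    common <- lapply(ENTITY_CLASS_CODES, function(cl) take(n_common))
    names(common) <- ENTITY_CLASS_CODES
    pools <- lapply(seq_len(config$n_diseases), function(d) {
      p <- lapply(ENTITY_CLASS_CODES, function(cl) {
        c(common[[cl]], take(ps - n_common))
      })
      names(p) <- ENTITY_CLASS_CODES
      p
    })
    roles <- purrr::map_dfr(seq_len(config$n_diseases), function(d) {
      purrr::map_dfr(ENTITY_CLASS_CODES, function(cl) {
        surf <- pools[[d]][[cl]]
        tibble::tibble(
          disease = sprintf("disease_%02d", d),
          class = cl, surface = surf,
          role = c("enabling_condition", "fault",
                   "consequence")[(seq_along(surf) - 1L) %% 3L + 1L]
        )
      })
    })
    docs <- list()
    pars <- list()
    mentions <- list()
    for (d in seq_len(config$n_diseases)) {
      for (r in seq_len(config$docs_per_disease)) {
        doc_id <- sprintf("d%02d_%02d", d, r)
        par_texts <- character(config$sections_per_doc)
        for (s in seq_len(config$sections_per_doc)) {
          sec <- sections[[(s - 1L) %% length(sections) + 1L]]
          k <- max(1L, stats::rpois(1, config$entities_per_paragraph))
          cls <- sample(sec$classes, k, replace = TRUE)
          surf <- vapply(cls, function(cl) {
            sample(pools[[d]][[cl]], 1)
          }, character(1), USE.NAMES = FALSE)
          par_id <- sprintf("%s:p%d", doc_id, s - 1L)
          text <- sec$open
          for (e in seq_len(k)) {
            if (e > 1) text <- paste0(text, sec$sep)
            mentions[[length(mentions) + 1L]] <- tibble::tibble(
              par_id = par_id, doc_id = doc_id,
              start = nchar(text), end = nchar(text) + nchar(surf[e]),
              surface = surf[e], class = cls[e]
            )
            text <- paste0(text, surf[e])
          }
          par_texts[s] <- paste0(text, sec$close)
        }
        doc_text <- paste(par_texts, collapse = "\n\n")
        starts <- cumsum(c(0L, utils::head(nchar(par_texts) + 2L, -1)))
        docs[[length(docs) + 1L]] <- tibble::tibble(
          doc_id = doc_id,
          title = sprintf("disease_%02d case %d", d, r),
          text = doc_text
        )
        pars[[length(pars) + 1L]] <- tibble::tibble(
          par_id = sprintf("%s:p%d", doc_id,
                           seq_len(config$sections_per_doc) - 1L),
          doc_id = doc_id,
          order_index = seq_len(config$sections_per_doc) - 1L,
          text = par_texts,
          start = starts,
          end = starts + nchar(par_texts)
        )
      }
    }
    corpus <- med_corpus(dplyr::bind_rows(docs), dplyr::bind_rows(pars))
    planted <- dplyr::bind_rows(mentions)
    used <- dplyr::distinct(
      planted[, c("surface", "class")]
    ) |> dplyr::arrange(.data$surface)
    labels <- tibble::tibble(
      doc_id = corpus$documents$doc_id,
      disease = sprintf(
        "disease_%02d",
        rep(seq_len(config$n_diseases), each = config$docs_per_disease)
      )
    )
    comp <- key_cooccurrence_components(corpus$paragraphs$par_id, planted)
    list(
      corpus = corpus,
      gazetteer = used,
      truth = list(
        doc_labels = labels,
        planted_mentions = planted,
        cooccurrence_components = comp,
        roles = roles
      ),
      config = config
    )
  })
}

# partition of paragraph ids into components connected by shared keys
# (bipartite paragraph-key graph; paragraphs without keys are singletons)
key_cooccurrence_components <- function(par_ids, mentions) {
  if (nrow(mentions) == 0) {
    return(lapply(sort(par_ids), identity))
  }
  keys <- paste(mentions$class, normalize_surface(mentions$surface),
                sep = ":")
  edges <- data.frame(
    from = paste0("p\r", mentions$par_id),
    to = paste0("k\r", keys)
  )
  verts <- data.frame(name = unique(c(
    paste0("p\r", par_ids), edges$to
  )))
  g <- igraph::graph_from_data_frame(unique(edges), directed = FALSE,
                                     vertices = verts)
  mem <- igraph::components(g)$membership
  pmem <- mem[paste0("p\r", par_ids)]
  blocks <- split(par_ids, pmem)
  blocks <- lapply(blocks, sort)
  unname(blocks[order(vapply(blocks, min, character(1)))])
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between a ground-truth and a predicted
#' partition, 1 for identical partitions (including the degenerate
#' single-block case), around 0 for random agreement.
#'
#' @param truth,predicted Named vectors of labels, or tibbles with an id
#'   column followed by a label column. Ids must match.
#' @return ARI in `[-1, 1]`.
#' @export
recovery_metrics <- function(truth, predicted) {
  as_named <- function(x) {
    if (is.data.frame(x)) stats::setNames(x[[2]], x[[1]]) else x
  }
  truth <- as_named(truth)
  predicted <- as_named(predicted)
  if (!is.null(names(truth)) || !is.null(names(predicted))) {
    if (is.null(names(truth)) || is.null(names(predicted)) ||
        !setequal(names(truth), names(predicted))) {
      stop("truth and predicted must cover the same elements", call. = FALSE)
    }
    predicted <- predicted[names(truth)]
  } else if (length(truth) != length(predicted)) {
    stop("truth and predicted must cover the same elements", call. = FALSE)
  }
  if (length(unique(truth)) == 1 && length(unique(predicted)) == 1) {
    return(1) # both trivial one-block partitions agree perfectly
  }
  mclust::adjustedRandIndex(as.character(truth), as.character(predicted))
}

#' Convert a block partition to a membership vector
#'
#' @param blocks List of character vectors (disjoint blocks).
#' @return Named integer vector: element -> block index.
#' @export
partition_membership <- function(blocks) {
  ids <- unlist(blocks, use.names = FALSE)
  mem <- rep(seq_along(blocks), vapply(blocks, length, integer(1)))
  stats::setNames(mem, ids)
}
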