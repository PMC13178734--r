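#' Pipeline run configuration
#'
#' Defaults follow the system's interactive settings: similarity threshold
#' 0.5 for both graph levels and a maximum constellation size of 10.
#'
#' @param corpus_path,gazetteer_path Optional input file paths (JSONL
#'   corpus, TSV gazetteer); alternatively pass objects to
#'   [run_pipeline()] directly.
#' @param out_dir Optional output directory for [write_bundle()].
#' @param theta_doc Document-graph similarity threshold in `[0, 1]`.
#' @param theta Paragraph-graph similarity threshold in `[0, 1]`.
#' @param max_size Maximum constellation size.
#' @param n_topics Number of topics; `NULL` picks
#'   `max(1, min(8, round(sqrt(n_docs))))`.
#' @param k Keywords per topic.
#' @param dim Embedding dimension.
#' @param h_t Profile height unit.
#' @param R Star-map radius.
#' @param focus Optional focus: `"surface:class"` for an entity or
#'   `"mes:<id>"` for an entity set; `NULL` profiles the most frequent
#'   entity key.
#' @param seed Integer seed for every stochastic stage.
#' @return A `med_run_config` list.
#' @export
run_config <- function(corpus_path = NULL, gazetteer_path = NULL,
                       out_dir = NULL, theta_doc = 0.5, theta = 0.5,
                       max_size = 10L, n_topics = NULL, k = 10L,
                       dim = 256L, h_t = 1, R = 1, focus = NULL,
                       seed = 1L) {
  stopifnot(
    theta_doc >= 0, theta_doc <= 1, theta >= 0, theta <= 1,
    max_size >= 1, k >= 1, dim >= 8, h_t > 0, R > 0
  )
  structure(
    list(
      corpus_path = corpus_path, gazetteer_path = gazetteer_path,
      out_dir = out_dir, theta_doc = theta_doc, theta = theta,
      max_size = as.integer(max_size),
      n_topics = if (is.null(n_topics)) NULL else as.integer(n_topics),
      k = as.integer(k), dim = as.integer(dim), h_t = h_t, R = R,
      focus = focus, seed = as.integer(seed)
    ),
    class = "med_run_config"
  )
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Path to a YAML/JSON file with [run_config()] fields.
#' @return A `med_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  do.call(run_config, vals)
}

parse_focus <- function(focus, sets) {
  if (is.null(focus)) {
    # default: most frequent entity key, ties by key string
    keys <- unlist(lapply(sets$keys, encode_keys), use.names = FALSE)
    if (length(keys) == 0) return(NULL)
    tab <- sort(table(keys), decreasing = TRUE)
    best <- names(tab)[order(-as.numeric(tab), names(tab))][1]
    return(focus_entity(decode_key_surface(best), decode_key_class(best)))
  }
  if (startsWith(focus, "mes:")) {
    return(focus_mes(substring(focus, 5)))
  }
  at <- regexpr(":[a-z]{3}$", focus)
  if (at < 0) {
    stop("focus must be 'surface:class' or 'mes:<id>'", call. = FALSE)
  }
  focus_entity(substr(focus, 1, at - 1), substring(focus, at + 1))
}

stage_log <- function(stage, t0, ...) {
  message(sprintf(
    "[medstars] %-12s %6.2fs  %s", stage,
    as.numeric(Sys.time()) - t0, paste0(...)
  ))
}

#' Run the full exploration pipeline
#'
#' Segment, extract, embed, cluster, build both graphs, partition, lay out,
#' grow the association tree and profile the focus — in order, logging
#' stage timings and counts to stderr. Deterministic given the
#' configuration seed.
#'
#' @param config A [run_config()].
#' @param corpus Optional [med_corpus()] (otherwise read from
#'   `config$corpus_path`).
#' @param gazetteer Optional compiled gazetteer (otherwise read from
#'   `config$gazetteer_path`).
#' @param quiet Suppress stage logging.
#' @return A `med_view_bundle`: serializable `space`, `starmap`, `tree` and
#'   `profile` view documents plus the underlying fitted objects under
#'   `$objects`.
#' @export
run_pipeline <- function(config, corpus = NULL, gazetteer = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "med_run_config"))
  log_ <- if (quiet) function(...) invisible() else stage_log
  t0 <- as.numeric(Sys.time())
  if (is.null(corpus)) {
    if (is.null(config$corpus_path)) {
      stop("no corpus given and no corpus_path configured", call. = FALSE)
    }
    corpus <- read_corpus(config$corpus_path)
  }
  if (is.null(gazetteer) && !is.null(config$gazetteer_path)) {
    gazetteer <- read_gazetteer(config$gazetteer_path)
  }
  corpus <- segment_corpus(corpus)
  log_("segment", t0, nrow(corpus$paragraphs), " paragraphs")
  if (nrow(corpus$documents) == 0) {
    return(empty_bundle(config))
  }
  mentions <- extract_corpus_entities(corpus, gazetteer)
  sets <- build_entity_sets(corpus, mentions)
  log_("extract", t0, nrow(mentions), " mentions, ",
       nrow(sets), " entity sets")
  doc_vec <- embed_documents(corpus, config$dim)
  par_vec <- embed_paragraphs(corpus, config$dim)
  log_("embed", t0, "dim ", config$dim)
  n_topics <- config$n_topics
  if (is.null(n_topics)) {
    n_topics <- max(1L, min(8L, as.integer(round(sqrt(nrow(corpus$documents))))))
  }
  topics <- fit_topics(corpus, n_topics, k = config$k, dim = config$dim,
                       seed = config$seed, vectors = doc_vec)
  log_("topics", t0, n_topics, " topics, diversity ",
       sprintf("%.3f", topics$diversity))
  doc_graph <- build_document_graph(corpus, doc_vec, config$theta_doc,
                                    topics)
  log_("doc graph", t0, nrow(doc_graph$edges), " edges")
  par_graph <- build_paragraph_graph(
    corpus, corpus$documents$doc_id, par_vec, doc_graph, config$theta
  )
  log_("par graph", t0, nrow(par_graph$intra_edges), " E_d, ",
       nrow(par_graph$sim_edges), " E_s")
  constellations <- partition_paragraph_graph(
    par_graph, config$max_size, config$seed
  )
  log_("partition", t0, nrow(constellations), " constellations")
  layout <- run_layout(
    par_graph, sets, pole_positions(config$R),
    layout_params(R = config$R, seed = config$seed)
  )
  log_("layout", t0, layout$iterations_used, " iterations")
  tree <- build_tree(sets[sets$total > 0, ])
  log_("tree", t0, length(branch_partition(tree)), " root children")
  focus <- parse_focus(config$focus, sets)
  profile <- if (is.null(focus)) NULL else
    build_profile(focus, sets, config$h_t)
  cards <- list()
  if (!is.null(profile) && nrow(profile$axes) > 0) {
    for (id in unique(profile$axes$mes_id)) {
      cards[[length(cards) + 1L]] <-
        card_doc(provenance_lookup(id, corpus, sets))
    }
  }
  log_("profile", t0, length(cards), " document cards")
  bundle <- structure(
    list(
      space = space_doc(doc_graph),
      starmap = starmap_doc(par_graph, constellations, layout, sets,
                            config),
      tree = as_tree_nodes(tree),
      profile = profile_doc(profile, cards),
      objects = list(
        corpus = corpus, mentions = mentions, sets = sets,
        topics = topics, doc_graph = doc_graph, par_graph = par_graph,
        constellations = constellations, layout = layout, tree = tree,
        profile = profile
      ),
      config = config
    ),
    class = "med_view_bundle"
  )
  bundle
}

empty_bundle <- function(config) {
  structure(
    list(
      space = list(threshold = config$theta_doc, nodes = list(),
                   edges = list()),
      starmap = list(threshold = config$theta, max_size = config$max_size,
                     R = config$R, poles = pole_doc(config$R),
                     constellations = list(), stars = list(),
                     intra_edges = list()),
      tree = list(kind = "ROOT", payload = NULL, color = "#000000",
                  collapsed = FALSE, children = list()),
      profile = NULL,
      objects = list(),
      config = config
    ),
    class = "med_view_bundle"
  )
}

#' @export
print.med_view_bundle <- function(x, ...) {
  cat(sprintf(
    "<med_view_bundle> %d space nodes, %d stars, %d tree root children\n",
    length(x$space$nodes), length(x$starmap$stars),
    length(x$tree$children)
  ))
  invisible(x)
}

# ---- view documents ------------------------------------------------------

# sequential luminance scale over an observed range; monotone, with a
# mid-scale value for singleton ranges
luminance_scale <- function(v) {
  if (length(v) == 0) return(numeric())
  lo <- min(v)
  hi <- max(v)
  if (hi == lo) return(rep(0.625, length(v)))
  0.35 + 0.55 * (v - lo) / (hi - lo)
}

space_doc <- function(doc_graph) {
  nodes <- doc_graph$nodes
  list(
    threshold = doc_graph$threshold,
    nodes = purrr::pmap(
      list(nodes$doc_id, nodes$size, nodes$topic, nodes$cluster,
           nodes$cluster_topic),
      function(id, size, topic, cluster, ct) {
        list(
          id = id, size = size,
          topic = if (is.na(topic)) NULL else topic,
          cluster = cluster,
          cluster_topic = if (is.na(ct)) NULL else ct
        )
      }
    ),
    edges = purrr::pmap(
      list(doc_graph$edges$from, doc_graph$edges$to,
           doc_graph$edges$weight),
      function(f, t, w) list(source = f, target = t, weight = w)
    )
  )
}

pole_doc <- function(R) {
  poles <- pole_positions(R)
  purrr::pmap(
    list(poles$class, poles$x, poles$y),
    function(cl, x, y) list(class = cl, x = x, y = y)
  )
}

starmap_doc <- function(par_graph, constellations, layout, sets, config) {
  member <- constellation_membership(constellations)
  fill <- luminance_scale(constellations$star_count)
  totals <- sets$total[match(layout$positions$par_id, sets$mes_id)]
  border <- luminance_scale(totals)
  pos <- layout$positions
  list(
    threshold = par_graph$threshold,
    max_size = config$max_size,
    R = config$R,
    poles = pole_doc(config$R),
    constellations = purrr::pmap(
      list(constellations$id, constellations$star_count,
           fill, constellations$members),
      function(id, sc, lum, members) {
        list(id = id, star_count = sc, fill_luminance = lum,
             members = as.list(members))
      }
    ),
    stars = purrr::pmap(
      list(pos$par_id, pos$x, pos$y,
           member$constellation[match(pos$par_id, member$par_id)],
           totals, border,
           par_graph$nodes$doc_id[match(pos$par_id,
                                        par_graph$nodes$par_id)]),
      function(id, x, y, cons, total, lum, doc_id) {
        list(id = id, constellation = cons, x = x, y = y,
             entity_total = total, border_luminance = lum,
             doc_id = doc_id)
      }
    ),
    intra_edges = purrr::pmap(
      list(par_graph$intra_edges$from, par_graph$intra_edges$to),
      function(f, t) list(source = f, target = t)
    )
  )
}

profile_doc <- function(profile, cards = list()) {
  if (is.null(profile)) return(NULL)
  focus <- profile$focus
  axes <- profile$axes
  axis_ids <- unique(axes$mes_id[order(axes$axis)])
  list(
    focus = list(
      kind = focus$kind,
      surface = focus$surface, class = focus$class,
      mes_id = focus$mes_id
    ),
    focal_class = profile$focal_class,
    h_t = profile$h_t,
    donut = purrr::pmap(
      list(profile$donut$class, profile$donut$fraction),
      function(cl, f) list(class = cl, fraction = f)
    ),
    axes = purrr::map(axis_ids, function(id) {
      a <- axes[axes$mes_id == id, ]
      list(
        axis = a$axis[1], mes_id = id, mp_id = a$par_id[1],
        doc_id = a$doc_id[1],
        counts = stats::setNames(as.list(a$n), a$class),
        heights = stats::setNames(as.list(a$height), a$class)
      )
    }),
    cards = cards
  )
}

card_doc <- function(card) {
  list(
    doc_id = card$doc_id,
    text = card$text,
    spans = purrr::pmap(
      list(card$spans$start, card$spans$end, card$spans$class),
      function(s, e, cl) list(start = s, end = e, class = cl)
    ),
    anchor = if (is.na(card$anchor)) NULL else card$anchor,
    active_class_filter = card$active_class_filter
  )
}

# ---- validation ----------------------------------------------------------

fail_if <- function(cond, ...) {
  if (cond) stop("view validation: ", ..., call. = FALSE)
}

#' Validate a view document against its published structure
#'
#' Structural validation of the exported JSON documents: required fields,
#' field types, resolvable cross-references and arithmetic invariants
#' (donut fractions summing to one, luminance in `[0, 1]`).
#'
#' @param doc A view document (the R list form, or a path to JSON).
#' @param which One of `"space"`, `"starmap"`, `"tree"`, `"profile"`.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_view <- function(doc, which) {
  if (is.character(doc) && length(doc) == 1) {
    doc <- jsonlite::fromJSON(doc, simplifyVector = FALSE)
  }
  which <- match.arg(which, c("space", "starmap", "tree", "profile"))
  if (which == "space") {
    fail_if(!all(c("threshold", "nodes", "edges") %in% names(doc)),
            "space view missing fields")
    ids <- vapply(doc$nodes, `[[`, "", "id")
    fail_if(anyDuplicated(ids) > 0, "duplicate space node id")
    for (e in doc$edges) {
      fail_if(!all(c(e$source, e$target) %in% ids),
              "space edge endpoint unresolved")
      fail_if(e$weight <= doc$threshold, "space edge at or below threshold")
    }
  } else if (which == "starmap") {
    need <- c("threshold", "max_size", "R", "poles", "constellations",
              "stars", "intra_edges")
    fail_if(!all(need %in% names(doc)), "starmap missing fields")
    fail_if(length(doc$poles) != 9, "starmap must have 9 poles")
    cons_ids <- vapply(doc$constellations, `[[`, numeric(1), "id")
    star_ids <- vapply(doc$stars, `[[`, "", "id")
    fail_if(anyDuplicated(star_ids) > 0, "duplicate star id")
    for (s in doc$stars) {
      fail_if(!s$constellation %in% cons_ids,
              "star references unknown constellation")
      fail_if(sqrt(s$x^2 + s$y^2) > doc$R + 1e-9, "star outside the disc")
      fail_if(s$border_luminance < 0 || s$border_luminance > 1,
              "border luminance out of range")
    }
    for (co in doc$constellations) {
      fail_if(co$star_count > doc$max_size, "constellation exceeds cap")
      fail_if(co$fill_luminance < 0 || co$fill_luminance > 1,
              "fill luminance out of range")
      fail_if(!all(unlist(co$members) %in% star_ids),
              "constellation member unresolved")
    }
    for (e in doc$intra_edges) {
      fail_if(!all(c(e$source, e$target) %in% star_ids),
              "intra edge endpoint unresolved")
    }
  } else if (which == "tree") {
    check_node <- function(n) {
      fail_if(!all(c("kind", "color", "collapsed", "children") %in%
                     names(n)), "tree node missing fields")
      fail_if(!n$kind %in% c("ROOT", "BRANCH", "MES_NODE", "ME_NODE"),
              "unknown tree node kind")
      for (ch in n$children) check_node(ch)
    }
    fail_if(doc$kind != "ROOT", "tree must start at ROOT")
    check_node(doc)
    ids <- c()
    walk <- function(n) {
      if (n$kind == "MES_NODE") ids <<- c(ids, n$payload$mes_id)
      for (ch in n$children) walk(ch)
    }
    walk(doc)
    fail_if(anyDuplicated(ids) > 0, "MES appears more than once in tree")
  } else {
    if (is.null(doc)) return(invisible(TRUE))
    fail_if(!all(c("focus", "donut", "axes") %in% names(doc)),
            "profile missing fields")
    fr <- vapply(doc$donut, `[[`, numeric(1), "fraction")
    if (length(fr) > 0 && length(doc$axes) > 0) {
      fail_if(abs(sum(fr) - 1) > 1e-9, "donut fractions must sum to 1")
    }
    for (a in doc$axes) {
      fail_if(!all(c("mes_id", "mp_id", "doc_id", "counts", "heights")
                   %in% names(a)), "axis missing fields")
    }
  }
  invisible(TRUE)
}

#' Export one view of a bundle as JSON
#'
#' The document is validated before writing; serialization is canonical
#' (fixed key order, no rounding) so identical bundles produce
#' byte-identical files. Luminance encodings in the star map are monotone:
#' constellation fill luminance increases with star count and star border
#' luminance with entity total.
#'
#' @param bundle A `med_view_bundle` from [run_pipeline()].
#' @param which One of `"space"`, `"starmap"`, `"tree"`, `"profile"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_view <- function(bundle, which, path) {
  stopifnot(inherits(bundle, "med_view_bundle"))
  which <- match.arg(which, c("space", "starmap", "tree", "profile"))
  doc <- bundle[[which]]
  validate_view(doc, which)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           null = "null")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, useBytes = TRUE)
  invisible(path)
}

#' Export every view of a bundle
#'
#' Writes `space.json`, `starmap.json`, `tree.json` and (when a focus was
#' profiled) `profile.json` into `dir`.
#'
#' @param bundle A `med_view_bundle`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  views <- c("space", "starmap", "tree")
  if (!is.null(bundle$profile)) views <- c(views, "profile")
  paths <- vapply(views, function(v) {
    p <- file.path(dir, paste0(v, ".json"))
    export_view(bundle, v, p)
    p
  }, character(1))
  invisible(paths)
}
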