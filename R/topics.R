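#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

# evaluate expr under a temporary RNG seed, restoring global RNG state
with_rng_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  expr
}

# spherical k-means on (assumed unit) rows with seeded k-means++ init
spherical_kmeans <- function(x, k, seed, nstart = 50L, iter_max = 300L) {
  n <- nrow(x)
  stopifnot(k >= 1, k <= n)
  norms <- sqrt(rowSums(x^2))
  x <- x / ifelse(norms == 0, 1, norms)
  run_once <- function() {
    # k-means++ style: distance d = 1 - cosine
    centers <- matrix(0, k, ncol(x))
    first <- sample.int(n, 1)
    centers[1, ] <- x[first, ]
    if (k > 1) {
      for (j in 2:k) {
        sims <- x %*% t(centers[seq_len(j - 1), , drop = FALSE])
        d <- 1 - apply(sims, 1, max)
        d[d < 0] <- 0
        pick <- if (sum(d) == 0) sample.int(n, 1) else
          sample.int(n, 1, prob = d)
        centers[j, ] <- x[pick, ]
      }
    }
    assign <- rep(0L, n)
    for (it in seq_len(iter_max)) {
      sims <- x %*% t(centers)
      new_assign <- max.col(sims, ties.method = "first")
      # re-seed empty clusters with the worst-served point
      for (j in seq_len(k)) {
        if (!any(new_assign == j)) {
          far <- which.min(apply(sims, 1, max))
          new_assign[far] <- j
          sims[far, ] <- -Inf
        }
      }
      if (identical(new_assign, assign)) break
      assign <- new_assign
      for (j in seq_len(k)) {
        cj <- colSums(x[assign == j, , drop = FALSE])
        nc <- sqrt(sum(cj^2))
        centers[j, ] <- if (nc == 0) cj else cj / nc
      }
    }
    sims <- x %*% t(centers)
    obj <- sum(1 - sims[cbind(seq_len(n), assign)])
    list(assign = assign, obj = obj)
  }
  with_rng_seed(seed, {
    best <- NULL
    for (r in seq_len(nstart)) {
      res <- run_once()
      if (is.null(best) || res$obj < best$obj - 1e-12) best <- res
    }
    best$assign
  })
}

#' Cluster documents into topics
#'
#' Spherical k-means over unit embedding vectors with seeded k-means++-style
#' initialization (50 restarts, up to 300 iterations each). Every document
#' receives exactly one topic. Rows are processed in sorted-id order and
#' topics are relabeled by first occurrence, so the result is deterministic
#' given (inputs, seed) and invariant under permutation of the input rows up
#' to nothing at all — labels included.
#'
#' @param vectors Matrix of document embeddings, row names = doc ids.
#' @param n_topics Number of topics (1..number of documents).
#' @param seed Integer seed.
#' @return A `med_topic_model` with `assignments` (tibble `doc_id`, `topic`),
#'   `n_topics`; keywords/diversity unfilled until [topic_keywords()] /
#'   [fit_topics()].
#' @export
cluster_documents <- function(vectors, n_topics, seed = 1L) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  if (n_topics < 1 || n_topics > nrow(vectors)) {
    stop("n_topics must be between 1 and the number of documents",
      call. = FALSE
    )
  }
  vectors <- vectors[order(rownames(vectors)), , drop = FALSE]
  assign <- spherical_kmeans(vectors, n_topics, seed)
  relabel <- match(assign, unique(assign))
  structure(
    list(
      assignments = tibble::tibble(
        doc_id = rownames(vectors), topic = relabel
      ),
      n_topics = n_topics,
      k = NA_integer_,
      keywords = NULL,
      diversity = NA_real_
    ),
    class = "med_topic_model"
  )
}

#' @export
print.med_topic_model <- function(x, ...) {
  cat(sprintf(
    "<med_topic_model> %d documents, %d topics%s\n",
    nrow(x$assignments), x$n_topics,
    if (is.na(x$diversity)) "" else sprintf(", diversity %.3f", x$diversity)
  ))
  invisible(x)
}

#' Class-based TF-IDF topic keywords
#'
#' All tokens of a topic's documents are pooled into one pseudo-document and
#' each term t is scored `tf(t, topic) * log(1 + A / f(t))`, where `tf` is
#' t's count in the pool, `f(t)` its total count over all topics and `A` the
#' mean token count per topic. The top `k` terms per topic are returned,
#' score ties broken lexicographically.
#'
#' @param doc_tokens Named list: doc id -> character vector of tokens.
#' @param assignments Tibble (`doc_id`, `topic`) or named topic vector.
#' @param k Number of keywords per topic (>= 1).
#' @return Named list: topic -> character vector of up to `k` terms.
#' @export
topic_keywords <- function(doc_tokens, assignments, k = 10L) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (is.data.frame(assignments)) {
    assignments <- stats::setNames(assignments$topic, assignments$doc_id)
  }
  miss <- setdiff(names(assignments), names(doc_tokens))
  if (length(miss) > 0) {
    stop("no tokens for document(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  topics <- sort(unique(assignments))
  pools <- lapply(topics, function(tp) {
    unlist(doc_tokens[names(assignments)[assignments == tp]],
      use.names = FALSE
    )
  })
  names(pools) <- as.character(topics)
  total <- table(unlist(pools, use.names = FALSE))
  a_mean <- mean(vapply(pools, length, integer(1)))
  out <- lapply(pools, function(pool) {
    if (length(pool) == 0) return(character())
    tf <- table(pool)
    terms <- names(tf)
    score <- as.numeric(tf) * log(1 + a_mean / as.numeric(total[terms]))
    terms[order(-score, terms)][seq_len(min(k, length(terms)))]
  })
  out
}

#' Topic diversity
#'
#' Fraction of unique terms among all topics' top-k keyword lists; 1 iff the
#' lists are pairwise disjoint.
#'
#' @param keywords Named list of equal-length keyword vectors.
#' @return A number in (0, 1].
#' @export
topic_diversity <- function(keywords) {
  if (length(keywords) < 1) stop("need at least one topic", call. = FALSE)
  lens <- vapply(keywords, length, integer(1))
  if (any(lens == 0)) stop("empty keyword list", call. = FALSE)
  if (length(unique(lens)) != 1) {
    stop("keyword lists must have equal length", call. = FALSE)
  }
  all_terms <- unlist(keywords, use.names = FALSE)
  length(unique(all_terms)) / length(all_terms)
}

#' Fit a full topic model over a corpus
#'
#' Embeds documents with the default hashed embedder, clusters them with
#' [cluster_documents()], scores keywords with [topic_keywords()] and
#' records the topic diversity.
#'
#' @param corpus A [med_corpus()].
#' @param n_topics Number of topics.
#' @param k Keywords per topic.
#' @param dim Embedding dimension.
#' @param seed Integer seed.
#' @param vectors Optional precomputed document embedding matrix.
#' @return A `med_topic_model` with keywords and diversity filled in.
#' @export
fit_topics <- function(corpus, n_topics, k = 10L, dim = 256L, seed = 1L,
                       vectors = NULL) {
  stopifnot(inherits(corpus, "med_corpus"))
  if (is.null(vectors)) vectors <- embed_documents(corpus, dim)
  model <- cluster_documents(vectors, n_topics, seed)
  toks <- tokenize_text(corpus$documents$text)
  names(toks) <- corpus$documents$doc_id
  model$keywords <- topic_keywords(toks, model$assignments, k)
  model$k <- as.integer(k)
  lens <- vapply(model$keywords, length, integer(1))
  model$diversity <- if (length(unique(lens)) == 1 && all(lens > 0)) {
    topic_diversity(model$keywords)
  } else {
    all_terms <- unlist(model$keywords, use.names = FALSE)
    length(unique(all_terms)) / length(all_terms)
  }
  model
}

#' @exportS3Method generics::tidy
tidy.med_topic_model <- function(x, ...) {
  x$assignments
}

#' @exportS3Method generics::glance
glance.med_topic_model <- function(x, ...) {
  tibble::tibble(
    n_docs = nrow(x$assignments),
    n_topics = x$n_topics,
    k = x$k,
    diversity = x$diversity
  )
}
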