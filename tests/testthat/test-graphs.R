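# vectors with a prescribed Gram matrix (unit diagonal), via Cholesky
vectors_with_sims <- function(gram, ids) {
  L <- t(chol(gram))
  rownames(L) <- ids
  L
}

test_that("document graph links exactly the pairs above the threshold", {
  # 5 documents with prescribed pairwise similarities; the 10 sims are
  # checked with the cosine oracle before asserting on the edges
  ids <- paste0("d", 1:5)
  gram <- diag(5)
  sims <- c(0.6, 0.4, 0.2, 0.1, 0.55, 0.3, 0.15, 0.7, 0.05, 0.51)
  gram[upper.tri(gram)] <- sims
  gram <- gram + t(gram) - diag(diag(gram))
  vec <- vectors_with_sims(gram, ids)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(cosine_similarity(vec[i, ], vec[j, ]), gram[i, j],
                 tolerance = 1e-9)
  }
  docs <- tibble::tibble(doc_id = ids, title = NA_character_,
                         text = strrep("x", 1:5))
  corpus <- med_corpus(docs)
  dg <- build_document_graph(corpus, vec, theta_doc = 0.5)
  got <- sort(paste(dg$edges$from, dg$edges$to))
  # upper.tri fills column-major: d1d2=0.6, d2d4=0.55, d2d5=0.7, d4d5=0.51
  # are the four similarities strictly above 0.5
  want <- sort(c("d1 d2", "d2 d4", "d2 d5", "d4 d5"))
  expect_equal(got, want)
  expect_true(all(dg$edges$weight > 0.5))
  expect_equal(dg$nodes$size, 1:5)
})

test_that("document graph degenerate thresholds behave", {
  ids <- c("a", "b")
  vec <- rbind(c(1, 0), c(0, 1))
  rownames(vec) <- ids
  corpus <- med_corpus(tibble::tibble(
    doc_id = ids, title = NA_character_, text = c("aa", "bb")
  ))
  dg <- build_document_graph(corpus, vec, theta_doc = 0.9)
  expect_equal(nrow(dg$edges), 0)
  expect_equal(length(unique(dg$nodes$cluster)), 2)
  expect_error(
    build_document_graph(corpus, vec[1, , drop = FALSE], 0.5),
    "missing vector"
  )
})

test_that("paragraph graph builds E_d chains and strict E_s edges", {
  docs <- tibble::tibble(
    doc_id = c("d1", "d2"), title = NA_character_,
    text = c("a\n\nb\n\nc", "d\n\ne\n\nf")
  )
  corpus <- segment_corpus(med_corpus(docs), min_len = 1)
  pids <- corpus$paragraphs$par_id
  vec <- diag(6)
  rownames(vec) <- pids
  g <- build_paragraph_graph(corpus, c("d1", "d2"), vec, theta = 0.5)
  expect_equal(nrow(g$intra_edges), 4)  # two chains of 3
  expect_equal(nrow(g$sim_edges), 0)

  # one selected doc: no cross-document pairs at all
  g1 <- build_paragraph_graph(corpus, "d1", vec, theta = 0)
  expect_equal(nrow(g1$sim_edges), 0)
  expect_equal(nrow(g1$intra_edges), 2)

  expect_error(
    build_paragraph_graph(corpus, "nope", vec, theta = 0.5),
    "not in corpus"
  )
})

test_that("E_s keeps exactly the cross pairs strictly above theta", {
  # 2 docs x 2 MPs with prescribed cross similarities
  # cross sims: a1-b1 0.9, a1-b2 0.5, a2-b1 0.3, a2-b2 0.51
  docs <- tibble::tibble(
    doc_id = c("da", "db"), title = NA_character_,
    text = c("p\n\nq", "r\n\ns")
  )
  corpus <- segment_corpus(med_corpus(docs), min_len = 1)
  ids <- corpus$paragraphs$par_id  # da:p0 da:p1 db:p0 db:p1
  gram <- diag(4)
  gram[1, 3] <- 0.9; gram[1, 4] <- 0.5
  gram[2, 3] <- 0.3; gram[2, 4] <- 0.51
  gram[1, 2] <- 0.2; gram[3, 4] <- 0.2
  gram <- gram + t(gram) - diag(diag(gram))
  vec <- vectors_with_sims(gram, ids)
  g <- build_paragraph_graph(corpus, c("da", "db"), vec, theta = 0.5)
  expect_equal(nrow(g$sim_edges), 2)
  expect_equal(sort(round(g$sim_edges$weight, 6)), c(0.51, 0.9))
  # the 0.5 pair is excluded by strictness
  expect_false(any(abs(g$sim_edges$weight - 0.5) < 1e-9))
})

test_that("E_s candidates are gated by document-graph links", {
  docs <- tibble::tibble(
    doc_id = c("d1", "d2", "d3"), title = NA_character_,
    text = c("a", "b", "c")
  )
  corpus <- segment_corpus(med_corpus(docs), min_len = 1)
  pids <- corpus$paragraphs$par_id
  # all paragraphs identical -> any allowed cross pair has sim 1
  vec <- matrix(rep(c(1, 0), 3), ncol = 2, byrow = TRUE,
                dimnames = list(pids, NULL))
  dg <- structure(
    list(
      nodes = tibble::tibble(doc_id = c("d1", "d2", "d3")),
      edges = edge_tbl("d1", "d2", 0.9),
      threshold = 0.5
    ),
    class = "med_document_graph"
  )
  g <- build_paragraph_graph(corpus, docs$doc_id, vec, dg, theta = 0.5)
  linked_docs <- sort(unique(c(
    corpus$paragraphs$doc_id[match(g$sim_edges$from, pids)],
    corpus$paragraphs$doc_id[match(g$sim_edges$to, pids)]
  )))
  expect_equal(linked_docs, c("d1", "d2"))  # d3 unlinked -> no E_s
  # with no document edges among the selection, all pairs are candidates
  dg$edges <- dg$edges[0, ]
  g2 <- build_paragraph_graph(corpus, docs$doc_id, vec, dg, theta = 0.5)
  expect_equal(nrow(g2$sim_edges), 3)
})

test_that("partitioner solves the hand-checkable cases exactly", {
  # single node
  g0 <- mk_graph("solo", "d")
  p0 <- partition_paragraph_graph(g0, max_size = 5)
  expect_equal(p0$star_count, 1)

  # two triangles bridged by one weak edge: optimal cut is the bridge
  tri <- function(a, b, c) edge_tbl(c(a, a, b), c(b, c, c), 1)
  g <- mk_graph(sprintf("n%d", 1:6), rep("d", 6),
                sim = dplyr::bind_rows(
                  tri("n1", "n2", "n3"), tri("n4", "n5", "n6"),
                  edge_tbl("n3", "n4", 0.1)
                ))
  p <- partition_paragraph_graph(g, max_size = 3)
  expect_equal(sort(sapply(p$members, paste, collapse = ",")),
               c("n1,n2,n3", "n4,n5,n6"))
  expect_equal(graph_cut_weight(g, p), 0.1)
  # brute-force over all capped partitions confirms optimality
  w <- matrix(0, 6, 6, dimnames = list(sort(g$nodes$par_id),
                                       sort(g$nodes$par_id)))
  for (r in seq_len(nrow(g$sim_edges))) {
    e <- g$sim_edges[r, ]
    w[e$from, e$to] <- e$weight
    w[e$to, e$from] <- e$weight
  }
  expect_equal(graph_cut_weight(g, p), brute_min_cut(w, 3))

  # path of 12 unit edges, cap 10: one cut edge suffices
  ids <- sprintf("p%02d", 1:13)
  gp <- mk_graph(ids, rep("d", 13),
                 intra = edge_tbl(ids[-13], ids[-1], 1))
  pp <- partition_paragraph_graph(gp, max_size = 10)
  expect_equal(nrow(pp), 2)
  expect_equal(graph_cut_weight(gp, pp), 1)
})

test_that("partitions are valid: disjoint, covering, size-capped", {
  for (seed in 1:10) {
    g <- random_connected_graph(n = 14, seed = seed)
    p <- partition_paragraph_graph(g, max_size = 5, seed = seed)
    members <- unlist(p$members)
    expect_setequal(members, g$nodes$par_id)
    expect_equal(anyDuplicated(members), 0)
    expect_true(all(p$star_count <= 5))
    # sanity bound: never worse than cutting every edge
    expect_lte(graph_cut_weight(g, p), sum(g$sim_edges$weight))
  }
})

test_that("constellation order and membership are deterministic", {
  g <- random_connected_graph(n = 12, seed = 99)
  p1 <- partition_paragraph_graph(g, max_size = 4, seed = 5)
  p2 <- partition_paragraph_graph(g, max_size = 4, seed = 5)
  expect_identical(p1, p2)
  m <- constellation_membership(p1)
  expect_setequal(m$par_id, g$nodes$par_id)
})
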