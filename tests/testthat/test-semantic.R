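test_that("hashed embeddings are deterministic unit vectors", {
  v1 <- embed_text("patient reports persistent fever", dim = 64)
  v2 <- embed_text("patient reports persistent fever", dim = 64)
  expect_identical(v1, v2)
  expect_equal(sqrt(sum(v1^2)), 1, tolerance = 1e-9)
  expect_equal(embed_text("", dim = 64), numeric(64))
  expect_equal(embed_text("   \n", dim = 64), numeric(64))
})

test_that("texts hashing to disjoint buckets are orthogonal", {
  t1 <- "alpha bravo"
  t2 <- "delta echo"
  b1 <- hash_bucket(c("alpha", "bravo"), 64)
  b2 <- hash_bucket(c("delta", "echo"), 64)
  # verify the bucket lists really are disjoint before asserting on cosine
  expect_length(intersect(b1, b2), 0)
  expect_equal(cosine_similarity(embed_text(t1, 64), embed_text(t2, 64)), 0)
})

test_that("cosine similarity obeys the arithmetic and conventions", {
  u <- c(1, 2, 2) / 3
  v <- c(2, 1, 2) / 3
  expect_equal(cosine_similarity(u, v), 8 / 9, tolerance = 1e-12)
  expect_equal(cosine_similarity(u, u), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(numeric(3), u), 0)
  expect_error(cosine_similarity(c(1, 0), c(1, 0, 0)), "mismatch")
})

test_that("CJK characters tokenize singly, letter runs whole", {
  toks <- tokenize_text("fever 发热 ongoing")[[1]]
  expect_equal(toks, c("fever", "发", "热", "ongoing"))
})

test_that("document clustering is deterministic and recovers blobs", {
  # two far-separated synthetic blobs -> exact recovery up to relabeling
  gen <- generate_corpus(synth_config(n_diseases = 2, docs_per_disease = 5,
                                      overlap_fraction = 0, seed = 7))
  vec <- embed_documents(gen$corpus, 128)
  tm <- cluster_documents(vec, 2, seed = 3)
  truth <- stats::setNames(gen$truth$doc_labels$disease,
                           gen$truth$doc_labels$doc_id)
  pred <- stats::setNames(tm$assignments$topic, tm$assignments$doc_id)
  expect_equal(recovery_metrics(truth, pred), 1.0)
  # identical seed, permuted input rows -> identical result
  tm2 <- cluster_documents(vec[sample(nrow(vec)), ], 2, seed = 3)
  expect_identical(tm$assignments, tm2$assignments)
})

test_that("clustering handles degenerate topic counts", {
  vecs <- matrix(rep(c(1, 0, 0, 0), 5), nrow = 5, byrow = TRUE,
                 dimnames = list(paste0("d", 1:5), NULL))
  tm <- cluster_documents(vecs, 1, seed = 1)
  expect_equal(unique(tm$assignments$topic), 1)
  expect_error(cluster_documents(vecs, 6, seed = 1), "n_topics")
})

test_that("every document gets its own topic when n_topics = n_docs", {
  vecs <- diag(4)
  rownames(vecs) <- paste0("d", 1:4)
  tm <- cluster_documents(vecs, 4, seed = 2)
  expect_equal(sort(unique(tm$assignments$topic)), 1:4)
  expect_equal(anyDuplicated(tm$assignments$topic), 0)
})

test_that("class-based TF-IDF keywords follow the score formula", {
  # topics {c1: [a,a,b], c2: [b,c]}: evaluated by hand, "a" tops c1 and
  # "c" tops c2 (b is shared and down-weighted)
  toks <- list(d1 = c("a", "a", "b"), d2 = c("b", "c"))
  assign <- tibble::tibble(doc_id = c("d1", "d2"), topic = c(1, 2))
  kw <- topic_keywords(toks, assign, k = 1)
  expect_equal(kw[["1"]], "a")
  expect_equal(kw[["2"]], "c")
  # a term occurring only in one topic scores there and nowhere else
  kw2 <- topic_keywords(toks, assign, k = 3)
  expect_false("a" %in% kw2[["2"]])
  # identical token multisets give identical lists
  kw3 <- topic_keywords(list(d1 = c("x", "y"), d2 = c("y", "x")), assign, 2)
  expect_identical(kw3[["1"]], kw3[["2"]])
  expect_error(topic_keywords(toks, assign, k = 0), "k must be")
  expect_error(
    topic_keywords(toks[1], assign, k = 1), "no tokens"
  )
})

test_that("topic diversity is the unique-term fraction", {
  expect_equal(
    topic_diversity(list(a = letters[1:5], b = letters[6:10])), 1.0
  )
  expect_equal(
    topic_diversity(list(a = letters[1:5], b = letters[1:5])), 0.5
  )
  expect_equal(
    topic_diversity(list(c("a", "b"), c("b", "c"), c("c", "d"))),
    4 / 6
  )
  expect_error(topic_diversity(list(character())), "empty")
  expect_error(topic_diversity(list()), "at least one")
})
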