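profile_sets <- function() {
  dplyr::bind_rows(
    mk_set("S1", c("e1", "e2")),
    mk_set("S2", c("e2", "e3")),
    mk_set("S3", "e4"),
    mk_set("S4", "e1")
  )
}

test_that("co-occurrence retrieval matches set membership", {
  sets <- profile_sets()
  # entity focus: all sets containing the key, in id order
  expect_equal(co_occurring_sets(focus_entity("e2", "sym"), sets)$mes_id,
               c("S1", "S2"))
  expect_equal(
    nrow(co_occurring_sets(focus_entity("nowhere", "sym"), sets)), 0
  )
  # MES focus: focal first, then sharers; disjoint sets excluded
  expect_equal(co_occurring_sets(focus_mes("S2"), sets)$mes_id,
               c("S2", "S1"))
  expect_equal(co_occurring_sets(focus_mes("S1"), sets)$mes_id,
               c("S1", "S2", "S4"))
  expect_error(co_occurring_sets(focus_mes("S99"), sets), "no entity set")
})

test_that("profile heights scale by h_t and the donut normalizes", {
  one <- dplyr::bind_rows(
    mk_set("P1", c("d1", "d2", "s1", "s2", "s3"),
           c("dis", "dis", "sym", "sym", "sym"))
  )
  pr <- build_profile(focus_mes("P1"), one, h_t = 10)
  hts <- pr$axes[pr$axes$n > 0, ]
  expect_equal(hts$height[hts$class == "dis"], 20)
  expect_equal(hts$height[hts$class == "sym"], 30)
  expect_equal(pr$donut$fraction[pr$donut$class == "dis"], 0.4)
  expect_equal(pr$donut$fraction[pr$donut$class == "sym"], 0.6)
  expect_equal(sum(pr$donut$fraction), 1, tolerance = 1e-12)
  expect_error(build_profile(focus_mes("P1"), one, h_t = 0), "positive")
})

test_that("entity focus with no occurrences yields an empty profile", {
  pr <- build_profile(focus_entity("ghost", "dru"), profile_sets())
  expect_equal(nrow(pr$axes), 0)
  expect_equal(nrow(pr$donut), 0)
  expect_equal(pr$focal_class, "dru")
})

test_that("donut equals normalized column sums over all axes", {
  sets <- dplyr::bind_rows(
    mk_set("A", c("x1", "x2"), c("dis", "sym")),
    mk_set("B", c("x1", "x3", "x4"), c("dis", "dru", "dru")),
    mk_set("C", c("x1", "x5"), c("dis", "bod"))
  )
  pr <- build_profile(focus_entity("x1", "dis"), sets)
  # hand-summed: dis 3, sym 1, dru 2, bod 1 -> total 7
  expect_equal(pr$donut$fraction[pr$donut$class == "dis"], 3 / 7)
  expect_equal(pr$donut$fraction[pr$donut$class == "dru"], 2 / 7)
  expect_equal(pr$donut$fraction[pr$donut$class == "sym"], 1 / 7)
  expect_equal(pr$donut$fraction[pr$donut$class == "bod"], 1 / 7)
  expect_equal(pr$focal_class, "dis")
})

test_that("profile arithmetic holds on random inputs", {
  set.seed(4242)
  for (rep in 1:60) {
    n_sets <- sample(2:6, 1)
    sets <- purrr::map_dfr(seq_len(n_sets), function(i) {
      k <- sample(1:6, 1)
      cls <- sample(ENTITY_CLASS_CODES, k, replace = TRUE)
      mk_set(sprintf("R%02d", i), paste0("s", sample(12, k)), cls)
    })
    target <- sets$keys[[1]][1, ]
    focus <- focus_entity(target$surface, target$class)
    h <- runif(1, 0.5, 5)
    pr <- build_profile(focus, sets, h_t = h)
    pr2 <- build_profile(focus, sets, h_t = 2 * h)
    if (nrow(pr$axes) > 0) {
      expect_equal(sum(pr$donut$fraction), 1, tolerance = 1e-12)
      expect_equal(pr2$axes$height, 2 * pr$axes$height, tolerance = 1e-12)
      # doubling h_t changes nothing else
      expect_identical(pr$axes[, setdiff(names(pr$axes), "height")],
                       pr2$axes[, setdiff(names(pr2$axes), "height")])
      expect_identical(pr$donut, pr2$donut)
      # axis order is a seedless-deterministic permutation
      pr3 <- build_profile(focus, sets, h_t = h)
      expect_identical(pr$axes, pr3$axes)
      expect_setequal(unique(pr$axes$mes_id),
                      co_occurring_sets(focus, sets)$mes_id)
    }
  }
})

test_that("provenance cards map spans to document offsets and filter", {
  docs <- tibble::tibble(
    doc_id = "D1", title = NA_character_,
    text = "intro text\n\nfever and chills, head ct done"
  )
  pars <- tibble::tibble(
    par_id = c("D1:p0", "D1:p1"), doc_id = "D1",
    order_index = 0:1,
    text = c("intro text", "fever and chills, head ct done"),
    start = c(0L, 12L), end = c(10L, 42L)
  )
  corpus <- med_corpus(docs, pars)
  m <- tibble::tibble(
    par_id = "D1:p1", start = c(0L, 10L, 18L), end = c(5L, 16L, 25L),
    surface = c("fever", "chills", "head ct"),
    class = c("sym", "sym", "ite")
  )
  sets <- build_entity_set("D1:p1", m, doc_id = "D1")
  card <- provenance_lookup("D1:p1", corpus, sets)
  expect_equal(nrow(card$spans), 3)
  expect_equal(
    substr(rep(card$text, 3), card$spans$start + 1, card$spans$end),
    c("fever", "chills", "head ct")
  )
  filt <- provenance_lookup("D1:p1", corpus, sets, class_filter = "sym")
  expect_equal(nrow(filt$spans), 2)
  expect_true(all(paste(filt$spans$start, filt$spans$end) %in%
                    paste(card$spans$start, card$spans$end)))
  expect_equal(filt$anchor, 12)
  none <- provenance_lookup("D1:p1", corpus, sets, class_filter = "dep")
  expect_equal(nrow(none$spans), 0)
  expect_true(is.na(none$anchor))
  expect_error(provenance_lookup("missing", corpus, sets), "no entity set")
})
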