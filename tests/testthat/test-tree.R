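tree_of <- function(sets) build_tree(dplyr::bind_rows(sets))

test_that("insertion grows branches exactly as the shared keys dictate", {
  t0 <- association_tree()
  t1 <- insert_entity_set(t0, mk_set("A", c("e1", "e2")))
  expect_equal(branch_partition(t1), list("A"))

  t2 <- insert_entity_set(t1, mk_set("B", c("e2", "e3")))
  expect_equal(branch_partition(t2), list(c("A", "B")))

  # disjoint set sits directly under the root, branch untouched
  t3 <- insert_entity_set(t2, mk_set("C", "e9"))
  expect_equal(branch_partition(t3), list(c("A", "B"), "C"))

  # chain merge: E bridges the A-B branch and singleton D
  t4 <- insert_entity_set(t3, mk_set("D", "e5"))
  t5 <- insert_entity_set(t4, mk_set("E", c("e3", "e5")))
  expect_equal(branch_partition(t5),
               list(c("A", "B", "D", "E"), "C"))
  # the merged branch promotes exactly the keys held by >= 2 members
  nodes <- as_tree_nodes(t5)
  branch <- nodes$children[[1]]
  shared <- vapply(
    Filter(function(n) n$kind == "ME_NODE", branch$children),
    function(n) n$payload$surface, ""
  )
  expect_equal(shared, c("e2", "e3", "e5"))
  expect_error(insert_entity_set(t5, mk_set("A", "zz")), "duplicate")
})

test_that("empty and disjoint collections build flat trees", {
  t <- tree_of(list())
  expect_equal(branch_partition(t), list())
  t3 <- tree_of(list(mk_set("A", "a"), mk_set("B", "b"), mk_set("C", "c")))
  expect_equal(branch_partition(t3), list("A", "B", "C"))
  nodes <- as_tree_nodes(t3)
  expect_equal(length(nodes$children), 3)
  expect_true(all(vapply(nodes$children, `[[`, "", "kind") == "MES_NODE"))
})

test_that("branch partition equals bipartite components (random cases)", {
  set.seed(202)
  for (rep in 1:150) {
    n_sets <- sample(2:6, 1)
    universe <- paste0("k", 1:5)
    key_list <- lapply(seq_len(n_sets), function(i) {
      sample(universe, sample(1:3, 1))
    })
    ids <- sprintf("S%02d", seq_len(n_sets))
    sets <- purrr::map2(ids, key_list, ~mk_set(.x, .y))
    got <- branch_partition(tree_of(sets))
    want <- uf_partition(ids, key_list)
    expect_equal(got, want)
  }
})

test_that("branch partition is invariant under insertion order", {
  set.seed(77)
  key_list <- list(c("a", "b"), c("b", "c"), "d", c("d", "e"), "f")
  ids <- paste0("S", 1:5)
  sets <- purrr::map2(ids, key_list, ~mk_set(.x, .y))
  ref <- branch_partition(tree_of(sets))
  for (i in 1:10) {
    perm <- sample(length(sets))
    expect_equal(branch_partition(tree_of(sets[perm])), ref)
  }
})

test_that("each MES id appears exactly once in the rendered tree", {
  sets <- list(
    mk_set("A", c("a", "b")), mk_set("B", c("b", "c")),
    mk_set("C", "z"), mk_set("D", c("c", "z"))
  )
  nodes <- as_tree_nodes(tree_of(sets))
  seen <- character()
  walk <- function(n) {
    if (n$kind == "MES_NODE") seen <<- c(seen, n$payload$mes_id)
    for (ch in n$children) walk(ch)
  }
  walk(nodes)
  expect_setequal(seen, c("A", "B", "C", "D"))
  expect_equal(anyDuplicated(seen), 0)
  # MES leaf children carry the collapsed flag for progressive disclosure
  mes_a <- Filter(function(n) n$kind == "MES_NODE", nodes$children[[1]]$children)[[1]]
  expect_true(all(vapply(mes_a$children, `[[`, TRUE, "collapsed")))
})

test_that("node colors are the weighted palette mixture", {
  pal <- default_class_palette()
  single <- mes_color(mk_set("X", c("a", "b"), "dru"), pal)
  expect_equal(unname(single),
               unname(unlist(pal[pal$class == "dru", c("r", "g", "b")])))
  two <- mes_color(mk_set("Y", c("a", "b"), c("dis", "sym")), pal)
  mid <- (unlist(pal[pal$class == "dis", c("r", "g", "b")]) +
            unlist(pal[pal$class == "sym", c("r", "g", "b")])) / 2
  expect_equal(unname(two), unname(mid))
  skew <- mes_color(
    mk_set("Z", c("a", "b", "c", "d"), c(rep("dis", 3), "dru")), pal
  )
  want <- 0.75 * unlist(pal[pal$class == "dis", c("r", "g", "b")]) +
    0.25 * unlist(pal[pal$class == "dru", c("r", "g", "b")])
  expect_equal(unname(skew), unname(want))
  expect_error(mes_color(build_entity_set("E", empty_mentions())), "empty")
})
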