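test_that("pole geometry follows the nine-point circle", {
  poles <- pole_positions(1)
  expect_equal(c(poles$x[1], poles$y[1]), c(1, 0))
  expect_equal(sum(poles$x), 0, tolerance = 1e-12)
  expect_equal(sum(poles$y), 0, tolerance = 1e-12)
  for (R in c(1, 2.5)) {
    p <- pole_positions(R)
    d <- as.matrix(stats::dist(cbind(p$x, p$y)))
    expect_equal(min(d[d > 0]), 2 * R * sin(pi / 9), tolerance = 1e-9)
    expect_equal(sqrt(p$x^2 + p$y^2), rep(R, 9), tolerance = 1e-12)
  }
  expect_error(pole_positions(0), "positive")
})

test_that("pole springs realize the weighted unit-force sum", {
  poles <- pole_positions(1)
  prm <- layout_params()
  g <- mk_graph("a", "d1")
  # all entities one class: unit force straight at that pole
  f <- compute_forces(tibble::tibble(par_id = "a", x = 0, y = 0), g,
                      mk_set("a", c("x", "y"), "dis"), poles, prm)
  expect_equal(c(f$fx, f$fy), c(1, 0), tolerance = 1e-12)
  # equal counts in all 9 classes at the center: symmetry cancels
  f9 <- compute_forces(tibble::tibble(par_id = "a", x = 0, y = 0), g,
                       mk_set("a", paste0("e", 1:9), ENTITY_CLASS_CODES),
                       poles, prm)
  expect_lt(sqrt(f9$fx^2 + f9$fy^2), 1e-12)
  # classes 0 and 1, one entity each: mean of the two pole directions
  f01 <- compute_forces(tibble::tibble(par_id = "a", x = 0, y = 0), g,
                        mk_set("a", c("p", "q"), c("dis", "sym")),
                        poles, prm)
  expect_equal(sqrt(f01$fx^2 + f01$fy^2), cos(pi / 9), tolerance = 1e-12)
  expect_equal(atan2(f01$fy, f01$fx), pi / 9, tolerance = 1e-12)
  # no entities: no spring force at all
  f0 <- compute_forces(tibble::tibble(par_id = "a", x = 0.3, y = 0.1), g,
                       empty_sets("a"), poles, prm)
  expect_equal(c(f0$fx, f0$fy), c(0, 0))
  # a star with no entity-set record is an error
  expect_error(
    compute_forces(tibble::tibble(par_id = "a", x = 0, y = 0), g,
                   empty_sets("b"), poles, prm),
    "no entity-set record"
  )
})

test_that("spring force never exceeds the unit force", {
  set.seed(31)
  poles <- pole_positions(1)
  prm <- layout_params()
  g <- mk_graph("s", "d")
  for (i in 1:50) {
    counts <- rpois(9, 2)
    if (sum(counts) == 0) counts[1] <- 1
    cls <- rep(ENTITY_CLASS_CODES, counts)
    sets <- mk_set("s", paste0("e", seq_along(cls)), cls)
    pos <- tibble::tibble(par_id = "s", x = runif(1, -1, 1) * 0.7,
                          y = runif(1, -1, 1) * 0.7)
    f <- compute_forces(pos, g, sets, poles, prm)
    expect_lte(sqrt(f$fx^2 + f$fy^2), prm$unit_force + 1e-12)
  }
})

test_that("gravity forces follow the edges and strict threshold", {
  poles <- pole_positions(1)
  prm <- layout_params()
  # isolated pair with one E_s edge of sim 0.8
  g <- mk_graph(c("a", "b"), c("d1", "d2"),
                sim = edge_tbl("a", "b", 0.8))
  f <- compute_forces(
    tibble::tibble(par_id = c("a", "b"), x = c(0, 1), y = c(0, 0)),
    g, empty_sets(c("a", "b")), poles, prm
  )
  expect_equal(f$fx, c(0.8, -0.8))
  expect_equal(f$fy, c(0, 0))
  # an E_s candidate at exactly theta contributes nothing
  g_at <- mk_graph(c("a", "b"), c("d1", "d2"),
                   sim = edge_tbl("a", "b", 0.5), threshold = 0.5)
  f_at <- compute_forces(
    tibble::tibble(par_id = c("a", "b"), x = c(0, 1), y = c(0, 0)),
    g_at, empty_sets(c("a", "b")), poles, prm
  )
  expect_equal(unlist(f_at[, c("fx", "fy")]), rep(0, 4),
               ignore_attr = TRUE)
  # intra edges pull with constant unit magnitude
  gi <- mk_graph(c("a", "b"), c("d1", "d1"),
                 intra = edge_tbl("a", "b", 1))
  fi <- compute_forces(
    tibble::tibble(par_id = c("a", "b"), x = c(0, 3), y = c(0, 4)),
    gi, empty_sets(c("a", "b")), poles, prm
  )
  expect_equal(fi$fx, c(0.6, -0.6))
  expect_equal(fi$fy, c(0.8, -0.8))
})

test_that("collision forces are reciprocal and handle coincidence", {
  poles <- pole_positions(1)
  prm <- layout_params(r_star = 0.1)
  g <- mk_graph(c("a", "b"), c("d1", "d2"))
  f <- compute_forces(
    tibble::tibble(par_id = c("a", "b"), x = c(0, 0.05), y = c(0, 0)),
    g, empty_sets(c("a", "b")), poles, prm
  )
  expect_equal(f$fx[1] + f$fx[2], 0, tolerance = 1e-12)
  expect_equal(f$fy[1] + f$fy[2], 0, tolerance = 1e-12)
  expect_equal(abs(f$fx[1]), prm$k_c * (0.2 - 0.05), tolerance = 1e-12)
  # coincident centers: deterministic opposite unit directions
  fc1 <- compute_forces(
    tibble::tibble(par_id = c("a", "b"), x = c(0, 0), y = c(0, 0)),
    g, empty_sets(c("a", "b")), poles, prm
  )
  fc2 <- compute_forces(
    tibble::tibble(par_id = c("a", "b"), x = c(0, 0), y = c(0, 0)),
    g, empty_sets(c("a", "b")), poles, prm
  )
  expect_identical(fc1, fc2)
  expect_equal(fc1$fx[1] + fc1$fx[2], 0, tolerance = 1e-12)
  expect_gt(sqrt(fc1$fx[1]^2 + fc1$fy[1]^2), 0)
})

test_that("layout converges onto the matching pole and stays in the disc", {
  poles <- pole_positions(1)
  for (j in c(1, 4, 7)) {
    cl <- ENTITY_CLASS_CODES[j]
    lay <- run_layout(mk_graph("s", "d"), mk_set("s", "e", cl), poles,
                      layout_params(seed = j))
    expect_true(lay$converged)
    p <- lay$positions
    d_own <- sqrt((p$x - poles$x[j])^2 + (p$y - poles$y[j])^2)
    expect_lt(d_own, 0.01)
    expect_lte(sqrt(p$x^2 + p$y^2), 1 + 1e-9)
  }
})

test_that("layout is bitwise deterministic and empty graphs are trivial", {
  g <- mk_graph(c("a", "b", "c"), c("d1", "d1", "d2"),
                intra = edge_tbl("a", "b", 1),
                sim = edge_tbl(c("a", "b"), c("c", "c"), c(0.8, 0.6)))
  sets <- dplyr::bind_rows(
    mk_set("a", "u", "dis"), mk_set("b", "v", "sym"),
    mk_set("c", "w", "dru")
  )
  l1 <- run_layout(g, sets, pole_positions(1), layout_params(seed = 17))
  l2 <- run_layout(g, sets, pole_positions(1), layout_params(seed = 17))
  expect_identical(l1$positions, l2$positions)
  expect_true(all(sqrt(l1$positions$x^2 + l1$positions$y^2) <= 1 + 1e-9))

  empty <- mk_graph(character(), character())
  l0 <- run_layout(empty, empty_sets(character()), pole_positions(1),
                   layout_params())
  expect_equal(nrow(l0$positions), 0)
  expect_true(l0$converged)
})

test_that("tidy and glance summarize a layout", {
  g <- mk_graph("a", "d1")
  lay <- run_layout(g, mk_set("a", "e", "dis"), pole_positions(1),
                    layout_params(seed = 2))
  expect_named(generics::tidy(lay), c("par_id", "x", "y"))
  gl <- generics::glance(lay)
  expect_equal(gl$n_stars, 1)
  expect_true(gl$converged)
})
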