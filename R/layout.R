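#' Positions of the nine entity-class poles
#'
#' The poles sit uniformly on the circular boundary of the star map, one per
#' entity class in ordinal order: pole j at
#' `(R cos(2*pi*j/9), R sin(2*pi*j/9))`, j = 0..8, so the `dis` pole is at
#' `(R, 0)`.
#'
#' @param R Map radius (> 0).
#' @return Tibble `class`, `ordinal`, `x`, `y` with attribute `radius = R`.
#' @export
pole_positions <- function(R = 1) {
  if (!is.numeric(R) || length(R) != 1 || R <= 0) {
    stop("R must be a single positive number", call. = FALSE)
  }
  cls <- entity_classes()
  ang <- 2 * pi * cls$ordinal / 9
  out <- tibble::tibble(
    class = cls$code, ordinal = cls$ordinal,
    x = R * cos(ang), y = R * sin(ang)
  )
  attr(out, "radius") <- R
  out
}

#' Layout parameters for the star-map force simulation
#'
#' @param R Map radius; poles sit on the circle of this radius.
#' @param unit_force Magnitude of the unit force (`||F||`) used by the
#'   intra-document link force, the similarity gravity and the pole springs.
#' @param alpha0 Initial step size (default `0.1 * R`).
#' @param rho Geometric cooling factor in (0, 1).
#' @param alpha_min Step-size floor (default `1e-4 * R`).
#' @param max_iter Maximum iterations.
#' @param k_c Collision stiffness (force per unit overlap), default
#'   `unit_force`.
#' @param r_star Uniform star radius used for collision, default `R / 50`.
#' @param tol Convergence tolerance on the maximum per-star displacement
#'   (default `1e-3 * R`).
#' @param seed Integer seed (initial placement and coincident-center
#'   collision directions).
#' @return A `med_layout_params` list.
#' @export
layout_params <- function(R = 1, unit_force = 1, alpha0 = 0.1 * R,
                          rho = 0.99, alpha_min = 1e-4 * R,
                          max_iter = 1000L, k_c = unit_force,
                          r_star = R / 50, tol = 1e-3 * R, seed = 1L) {
  stopifnot(
    R > 0, unit_force > 0, alpha0 > 0, rho > 0, rho < 1,
    alpha_min > 0, alpha_min < alpha0, max_iter >= 1, k_c > 0,
    r_star > 0, tol > 0
  )
  structure(
    list(
      R = R, unit_force = unit_force, alpha0 = alpha0, rho = rho,
      alpha_min = alpha_min, max_iter = as.integer(max_iter), k_c = k_c,
      r_star = r_star, tol = tol, seed = as.integer(seed)
    ),
    class = "med_layout_params"
  )
}

# deterministic pseudo-random angle for a coincident pair, from seed + ids
coincident_angle <- function(seed, id_a, id_b) {
  key <- paste(seed, min(id_a, id_b), max(id_a, id_b), sep = "\r")
  h <- 5381
  for (c in utf8ToInt(key)) h <- (h * 33 + c) %% 2147483647
  2 * pi * h / 2147483647
}

# precompute index structures for the force loop
layout_context <- function(graph, entity_sets, poles, params) {
  ids <- sort(graph$nodes$par_id)
  miss <- setdiff(ids, entity_sets$mes_id)
  if (length(miss) > 0) {
    stop("no entity-set record for paragraph(s): ",
      paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  counts <- mes_class_counts(entity_sets[match(ids, entity_sets$mes_id), ])
  cmat <- matrix(counts$n, nrow = length(ids), ncol = 9, byrow = TRUE)
  tot <- rowSums(cmat)
  wmat <- cmat / ifelse(tot == 0, 1, tot) # num_ij / num_i; zero rows stay 0
  edge_idx <- function(e, strict_theta = FALSE) {
    if (strict_theta && nrow(e) > 0) e <- e[e$weight > graph$threshold, ]
    list(
      i = match(e$from, ids), j = match(e$to, ids),
      w = if (nrow(e) > 0) e$weight else numeric()
    )
  }
  list(
    ids = ids,
    intra = edge_idx(graph$intra_edges),
    sim = edge_idx(graph$sim_edges, strict_theta = TRUE),
    weights = wmat,
    poles = as.matrix(poles[, c("x", "y")]),
    params = params
  )
}

# combined force field; p is an n x 2 position matrix aligned with ctx$ids
forces_matrix <- function(p, ctx) {
  n <- nrow(p)
  prm <- ctx$params
  f <- matrix(0, n, 2)
  pull <- function(i, j, mag) {
    # attraction of star i toward star j with the given magnitude
    d <- p[j, , drop = FALSE] - p[i, , drop = FALSE]
    len <- sqrt(rowSums(d^2))
    ok <- len > 0
    u <- d
    u[ok, ] <- d[ok, , drop = FALSE] / len[ok]
    u[!ok, ] <- 0
    for (r in seq_along(i)) {
      f[i[r], ] <<- f[i[r], ] + mag[r] * u[r, ]
      f[j[r], ] <<- f[j[r], ] - mag[r] * u[r, ]
    }
  }
  if (length(ctx$intra$i) > 0) {
    pull(ctx$intra$i, ctx$intra$j, rep(prm$unit_force, length(ctx$intra$i)))
  }
  if (length(ctx$sim$i) > 0) {
    pull(ctx$sim$i, ctx$sim$j, prm$unit_force * ctx$sim$w)
  }
  # pole springs, Eq-3 style: weight num_ij/num_i toward each class pole
  for (jj in seq_len(9)) {
    w <- ctx$weights[, jj]
    act <- which(w > 0)
    if (length(act) == 0) next
    d <- matrix(ctx$poles[jj, ], length(act), 2, byrow = TRUE) -
      p[act, , drop = FALSE]
    len <- sqrt(rowSums(d^2))
    ok <- len > 0
    u <- d
    u[ok, ] <- d[ok, , drop = FALSE] / len[ok]
    u[!ok, ] <- 0
    f[act, ] <- f[act, ] + prm$unit_force * w[act] * u
  }
  # pairwise collision: linear in overlap, reciprocal
  if (n > 1) {
    dm <- as.matrix(stats::dist(p))
    rsum <- 2 * prm$r_star
    idx <- which(upper.tri(dm) & dm < rsum, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      d <- dm[i, j]
      mag <- prm$k_c * (rsum - d)
      if (d > 0) {
        u <- (p[i, ] - p[j, ]) / d
      } else {
        a <- coincident_angle(prm$seed, ctx$ids[i], ctx$ids[j])
        u <- c(cos(a), sin(a))
        if (ctx$ids[i] > ctx$ids[j]) u <- -u
      }
      f[i, ] <- f[i, ] + mag * u
      f[j, ] <- f[j, ] - mag * u
    }
  }
  f
}

#' Compute the combined force on each star
#'
#' The combined force is the sum of three components: gravity (the constant
#' `||F||`-magnitude attraction along intra-document edges plus the
#' similarity-scaled attraction along similarity edges above the strict
#' threshold), the nine pole springs weighted `num_ij / num_i` (zero for
#' entity-free stars), and pairwise collision repulsion linear in overlap.
#' A star exactly at a target contributes zero for that term.
#'
#' @param stars Tibble `par_id`, `x`, `y` — current star positions; must
#'   cover the graph's nodes.
#' @param graph A `med_paragraph_graph`.
#' @param entity_sets Entity sets from [build_entity_sets()] (every star
#'   needs a record; an empty set is fine).
#' @param poles A pole set from [pole_positions()].
#' @param params A [layout_params()] object.
#' @return Tibble `par_id`, `fx`, `fy`.
#' @export
compute_forces <- function(stars, graph, entity_sets, poles, params) {
  stopifnot(inherits(graph, "med_paragraph_graph"))
  ctx <- layout_context(graph, entity_sets, poles, params)
  pos <- as.matrix(stars[match(ctx$ids, stars$par_id), c("x", "y")])
  if (anyNA(pos)) stop("stars must cover every graph node", call. = FALSE)
  f <- forces_matrix(pos, ctx)
  tibble::tibble(par_id = ctx$ids, fx = f[, 1], fy = f[, 2])
}

#' Run the star-map layout simulation
#'
#' Stars start at seeded uniform positions inside the disc of radius `R/2`
#' and follow damped explicit steps
#' `position <- clamp_to_disc(position + alpha_t * F_combined)` with
#' geometric cooling `alpha_t = max(alpha0 * rho^t, alpha_min)`, stopping
#' when the maximum per-star displacement drops below `tol` or after
#' `max_iter` iterations. Fully deterministic given the seed; no star ever
#' leaves the closed disc of radius `R`.
#'
#' @inheritParams compute_forces
#' @return A `med_star_layout`: list with `positions` (tibble `par_id`, `x`,
#'   `y`), `iterations_used`, `converged`, plus the poles and params used.
#' @export
run_layout <- function(graph, entity_sets, poles = pole_positions(),
                       params = layout_params()) {
  stopifnot(inherits(graph, "med_paragraph_graph"))
  if (nrow(graph$nodes) == 0) {
    return(structure(
      list(
        positions = tibble::tibble(par_id = character(), x = numeric(),
                                   y = numeric()),
        iterations_used = 0L, converged = TRUE,
        poles = poles, params = params
      ),
      class = "med_star_layout"
    ))
  }
  ctx <- layout_context(graph, entity_sets, poles, params)
  n <- length(ctx$ids)
  R <- params$R
  pos <- with_rng_seed(params$seed, {
    ang <- stats::runif(n, 0, 2 * pi)
    rad <- (R / 2) * sqrt(stats::runif(n))
    cbind(rad * cos(ang), rad * sin(ang))
  })
  clamp <- function(p) {
    len <- sqrt(rowSums(p^2))
    over <- len > R
    if (any(over)) p[over, ] <- p[over, , drop = FALSE] * (R / len[over])
    p
  }
  converged <- FALSE
  iters <- 0L
  for (t in seq_len(params$max_iter)) {
    alpha <- max(params$alpha0 * params$rho^(t - 1), params$alpha_min)
    f <- forces_matrix(pos, ctx)
    new_pos <- clamp(pos + alpha * f)
    disp <- sqrt(rowSums((new_pos - pos)^2))
    pos <- new_pos
    iters <- t
    if (max(disp) < params$tol) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(
      positions = tibble::tibble(par_id = ctx$ids, x = pos[, 1],
                                 y = pos[, 2]),
      iterations_used = iters, converged = converged,
      poles = poles, params = params
    ),
    class = "med_star_layout"
  )
}

#' @export
print.med_star_layout <- function(x, ...) {
  cat(sprintf(
    "<med_star_layout> %d stars, %d iterations, %s\n",
    nrow(x$positions), x$iterations_used,
    if (x$converged) "converged" else "not converged"
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.med_star_layout <- function(x, ...) {
  x$positions
}

#' @exportS3Method generics::glance
glance.med_star_layout <- function(x, ...) {
  tibble::tibble(
    n_stars = nrow(x$positions),
    iterations_used = x$iterations_used,
    converged = x$converged,
    R = x$params$R
  )
}
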