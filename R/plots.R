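#' Plot the document space view
#'
#' Documents as points sized by text length and colored by cluster, with
#' similarity edges above the threshold drawn between them; a planar
#' rendition of the space view. Positions come from a deterministic
#' circular arrangement per cluster (rendering is not the layout's job at
#' the document level).
#'
#' @param x A `med_document_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.med_document_graph <- function(x, ...) {
  nodes <- x$nodes
  # deterministic radial placement: clusters on an outer ring, members on
  # small rings around their cluster anchor
  k <- length(unique(nodes$cluster))
  anchor <- tibble::tibble(
    cluster = sort(unique(nodes$cluster)),
    ax = cos(2 * pi * (seq_len(k) - 1) / max(1, k)),
    ay = sin(2 * pi * (seq_len(k) - 1) / max(1, k))
  )
  nodes <- nodes |>
    dplyr::group_by(.data$cluster) |>
    dplyr::mutate(
      ang = 2 * pi * (dplyr::row_number() - 1) / dplyr::n(),
      px = anchor$ax[match(.data$cluster[1], anchor$cluster)] +
        0.25 * cos(.data$ang),
      py = anchor$ay[match(.data$cluster[1], anchor$cluster)] +
        0.25 * sin(.data$ang)
    ) |>
    dplyr::ungroup()
  edges <- x$edges |>
    dplyr::mutate(
      x = nodes$px[match(.data$from, nodes$doc_id)],
      y = nodes$py[match(.data$from, nodes$doc_id)],
      xend = nodes$px[match(.data$to, nodes$doc_id)],
      yend = nodes$py[match(.data$to, nodes$doc_id)]
    )
  ggplot() +
    geom_segment(
      data = edges,
      aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
          linewidth = .data$weight),
      color = "grey70"
    ) +
    geom_point(
      data = nodes,
      aes(x = .data$px, y = .data$py, size = .data$size,
          color = factor(.data$cluster))
    ) +
    scale_linewidth(range = c(0.2, 1), guide = "none") +
    coord_equal() +
    labs(color = "cluster", size = "characters") +
    theme_void()
}

#' Plot a star-map layout
#'
#' Stars at their converged positions, constellation lines along
#' intra-document edges, and the nine class poles on the boundary circle.
#'
#' @param layout A `med_star_layout`.
#' @param graph The `med_paragraph_graph` that was laid out.
#' @param constellations Optional partition from
#'   [partition_paragraph_graph()] for coloring.
#' @return A ggplot object.
#' @export
plot_star_map <- function(layout, graph, constellations = NULL) {
  pos <- layout$positions
  poles <- layout$poles
  R <- layout$params$R
  if (!is.null(constellations)) {
    mem <- constellation_membership(constellations)
    pos$constellation <- factor(
      mem$constellation[match(pos$par_id, mem$par_id)]
    )
  } else {
    pos$constellation <- factor(1)
  }
  edges <- graph$intra_edges |>
    dplyr::mutate(
      x = pos$x[match(.data$from, pos$par_id)],
      y = pos$y[match(.data$from, pos$par_id)],
      xend = pos$x[match(.data$to, pos$par_id)],
      yend = pos$y[match(.data$to, pos$par_id)]
    )
  ang <- seq(0, 2 * pi, length.out = 200)
  circle <- tibble::tibble(x = R * cos(ang), y = R * sin(ang))
  ggplot() +
    geom_path(data = circle, aes(x = .data$x, y = .data$y),
              color = "grey80") +
    geom_segment(
      data = edges,
      aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      color = "grey60"
    ) +
    geom_point(
      data = pos,
      aes(x = .data$x, y = .data$y, color = .data$constellation),
      size = 2
    ) +
    geom_text(
      data = poles,
      aes(x = 1.08 * .data$x, y = 1.08 * .data$y, label = .data$class),
      size = 3
    ) +
    coord_equal() +
    theme_void() +
    labs(color = "constellation")
}

#' @rdname plot_star_map
#' @param x A `med_star_layout`.
#' @param ... Passed on; `graph` and `constellations` are accepted.
#' @exportS3Method ggplot2::autoplot
autoplot.med_star_layout <- function(x, ...) {
  args <- list(...)
  if (is.null(args$graph)) {
    stop("autoplot for a layout needs the graph: autoplot(layout, graph = g)",
      call. = FALSE
    )
  }
  plot_star_map(x, args$graph, args$constellations)
}

#' Plot a focused sectional profile
#'
#' Polar stacked-area rendition of the profile: one axis per co-occurring
#' entity set, heights `N_ik * h_t`, classes colored with the shared
#' palette.
#'
#' @param x A `med_sectional_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.med_sectional_profile <- function(x, ...) {
  axes <- x$axes
  if (nrow(axes) == 0) {
    return(ggplot() + theme_void() +
             labs(title = "empty profile (focus occurs nowhere)"))
  }
  pal <- default_class_palette()
  cols <- stats::setNames(
    grDevices::rgb(pal$r, pal$g, pal$b), pal$class
  )
  ggplot(axes, aes(x = factor(.data$axis), y = .data$height,
                   fill = .data$class)) +
    geom_col(width = 0.95) +
    scale_fill_manual(values = cols) +
    coord_polar() +
    labs(x = "co-occurring entity set", y = "N_ik * h_t", fill = "class") +
    theme_minimal()
}
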