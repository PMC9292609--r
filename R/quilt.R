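# --- Delaunay triangulation (Bowyer-Watson) -------------------------------
# Small-n scattered-data triangulation used by the quilt plot; cells on a TGP
# number at most a few dozen, so the O(n^2) incremental algorithm is ample.

tri_ccw <- function(x, y, tri) {
  cross <- (x[tri[2]] - x[tri[1]]) * (y[tri[3]] - y[tri[1]]) -
    (y[tri[2]] - y[tri[1]]) * (x[tri[3]] - x[tri[1]])
  if (cross < 0) tri[c(1, 3, 2)] else tri
}

in_circumcircle <- function(x, y, tri, px, py) {
  ax <- x[tri[1]] - px; ay <- y[tri[1]] - py
  bx <- x[tri[2]] - px; by <- y[tri[2]] - py
  cx <- x[tri[3]] - px; cy <- y[tri[3]] - py
  det <- (ax * ax + ay * ay) * (bx * cy - cx * by) -
    (bx * bx + by * by) * (ax * cy - cx * ay) +
    (cx * cx + cy * cy) * (ax * by - bx * ay)
  det > 1e-12
}

delaunay <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3L)
  # degenerate geometry: all points collinear
  span <- max(abs(
    (x - x[1]) * (y[2] - y[1]) - (y - y[1]) * (x[2] - x[1])
  ))
  if (!is.finite(span) || span < 1e-9 * max(diff(range(x)), diff(range(y)), 1)) {
    tgp_abort("cells are collinear; cannot triangulate", "tgp_degenerate_geometry")
  }
  # super-triangle well outside the data
  cx <- mean(range(x)); cy <- mean(range(y))
  r <- max(diff(range(x)), diff(range(y)), 1) * 20
  xs <- c(x, cx - 2 * r, cx + 2 * r, cx)
  ys <- c(y, cy - r, cy - r, cy + 2 * r)
  tris <- list(tri_ccw(xs, ys, c(n + 1L, n + 2L, n + 3L)))
  for (p in seq_len(n)) {
    bad <- vapply(tris, function(t) in_circumcircle(xs, ys, t, xs[p], ys[p]),
                  logical(1))
    edges <- do.call(rbind, lapply(tris[bad], function(t) {
      rbind(sort(t[1:2]), sort(t[2:3]), sort(t[c(1, 3)]))
    }))
    tris <- tris[!bad]
    if (!is.null(edges)) {
      key <- paste(edges[, 1], edges[, 2])
      boundary <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
      for (e in seq_len(nrow(boundary))) {
        tris <- c(tris, list(tri_ccw(xs, ys, c(boundary[e, ], p))))
      }
    }
  }
  keep <- vapply(tris, function(t) all(t <= n), logical(1))
  do.call(rbind, tris[keep])
}

# Barycentric coordinates of (px, py) in triangle `tri`; NULL if outside.
barycentric <- function(x, y, tri, px, py, tol = 1e-9) {
  x1 <- x[tri[1]]; y1 <- y[tri[1]]
  x2 <- x[tri[2]]; y2 <- y[tri[2]]
  x3 <- x[tri[3]]; y3 <- y[tri[3]]
  det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
  l1 <- ((y2 - y3) * (px - x3) + (x3 - x2) * (py - y3)) / det
  l2 <- ((y3 - y1) * (px - x3) + (x1 - x3) * (py - y3)) / det
  l3 <- 1 - l1 - l2
  if (l1 >= -tol && l2 >= -tol && l3 >= -tol) c(l1, l2, l3) else NULL
}

#' Linearly interpolate scattered cell values onto a regular grid
#'
#' Piecewise-linear interpolation over a Delaunay triangulation of the cells;
#' grid points outside the convex hull are \code{NA} (masked, never
#' extrapolated). At a cell's own coordinates the grid reproduces the cell
#' value exactly, and along a hull edge the interpolant is linear between the
#' edge's cells.
#'
#' @param day_temp,night_temp,value Equal-length vectors of cell coordinates
#'   and values (>= 3 non-collinear cells).
#' @param resolution Grid points per axis (default 60).
#' @return Data frame \code{day_temp, night_temp, value} over the grid (NA
#'   outside the hull).
#' @export
quilt_grid <- function(day_temp, night_temp, value, resolution = 60) {
  stopifnot(length(day_temp) == length(night_temp),
            length(day_temp) == length(value))
  if (length(day_temp) < 3L) {
    tgp_abort("need >= 3 cells to interpolate", "tgp_degenerate_geometry")
  }
  tris <- delaunay(day_temp, night_temp)
  gx <- seq(min(day_temp), max(day_temp), length.out = resolution)
  gy <- seq(min(night_temp), max(night_temp), length.out = resolution)
  grid <- expand.grid(day_temp = gx, night_temp = gy)
  grid$value <- NA_real_
  for (i in seq_len(nrow(grid))) {
    for (t in seq_len(nrow(tris))) {
      l <- barycentric(day_temp, night_temp, tris[t, ],
                       grid$day_temp[i], grid$night_temp[i])
      if (!is.null(l)) {
        grid$value[i] <- sum(l * value[tris[t, ]])
        break
      }
    }
  }
  grid
}

#' Interpolate a value at arbitrary points over the cell scatter
#'
#' Same interpolant as \code{\link{quilt_grid}} evaluated at given points.
#'
#' @param day_temp,night_temp,value Cell coordinates and values.
#' @param at Data frame with \code{day_temp}, \code{night_temp} query columns.
#' @return Numeric vector (NA outside the convex hull).
#' @export
quilt_interpolate <- function(day_temp, night_temp, value, at) {
  tris <- delaunay(day_temp, night_temp)
  vapply(seq_len(nrow(at)), function(i) {
    for (t in seq_len(nrow(tris))) {
      l <- barycentric(day_temp, night_temp, tris[t, ],
                       at$day_temp[i], at$night_temp[i])
      if (!is.null(l)) return(sum(l * value[tris[t, ]]))
    }
    NA_real_
  }, numeric(1))
}

#' Quilt plot of a germination index over the plate
#'
#' The classic TGP visualization: day temperature on the x-axis, night
#' temperature on the y-axis and a germination index as the rasterized,
#' linearly interpolated z-axis, masked to the convex hull of the cells.
#'
#' @param cells Data frame with \code{day_temp}, \code{night_temp} and the
#'   index column.
#' @param value_col Name of the index column to plot.
#' @param resolution Grid points per axis.
#' @param title Plot title.
#' @return List with \code{plot} (a ggplot) and \code{grid} (the interpolated
#'   values; every plotted number is exportable).
#' @export
quilt_plot <- function(cells, value_col = "final_germination_proportion",
                       resolution = 60, title = value_col) {
  check_columns(cells, c("day_temp", "night_temp", value_col), "cell table")
  grid <- quilt_grid(cells$day_temp, cells$night_temp, cells[[value_col]],
                     resolution = resolution)
  p <- ggplot2::ggplot(grid[!is.na(grid$value), ],
                       ggplot2::aes(x = .data$day_temp, y = .data$night_temp,
                                    fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = value_col) +
    ggplot2::labs(x = "Day temperature (degC)", y = "Night temperature (degC)",
                  title = title) +
    ggplot2::theme_minimal()
  list(plot = p, grid = grid)
}

#' Monthly prediction plot for one or more scenarios
#'
#' Lines (with uncertainty ribbons where available) of predicted germination by
#' month, January to December, one colour per scenario.
#'
#' @param predictions One or a list of \code{\link{predict_monthly}} outputs.
#' @return A ggplot object.
#' @export
monthly_plot <- function(predictions) {
  if (is.data.frame(predictions)) predictions <- list(predictions)
  df <- do.call(rbind, predictions)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$month, y = .data$prediction,
                                   colour = .data$scenario,
                                   fill = .data$scenario)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = 1:12, labels = month.abb) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Predicted germination proportion") +
    ggplot2::theme_minimal()
}
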