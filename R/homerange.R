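#' Kernel utilization distribution
#'
#' Product-Gaussian kernel density estimate of an animal's space use from a
#' set of locations, with a single bandwidth `b` for both coordinates:
#' `f(c) = sum_i g((c1 - x_i)/b) g((c2 - y_i)/b) / (n b^2)`.
#'
#' @param points n x 2 matrix of locations (m).
#' @param bandwidth kernel bandwidth `b` in meters (> 0).
#' @param grid optional list with vectors `x`, `y` of cell-center
#'   coordinates; default is the point bounding box padded by `4 b` at 128
#'   cells per axis.
#' @param n_grid grid resolution per axis for the default grid.
#' @return object of class `kernel_ud`: list with `x`, `y`, `z` (density
#'   matrix, `length(x)` rows), `bandwidth`, `cell` (cell area).
#' @export
kernel_ud <- function(points, bandwidth, grid = NULL, n_grid = 128L) {
  points <- matrix(as.numeric(points), ncol = 2)
  n <- nrow(points)
  if (n < 1L) stop("need at least one location")
  if (!is.finite(bandwidth) || bandwidth <= 0) stop("bandwidth must be > 0")
  if (is.null(grid)) {
    xr <- range(points[, 1]) + c(-4, 4) * bandwidth
    yr <- range(points[, 2]) + c(-4, 4) * bandwidth
    grid <- list(x = seq(xr[1], xr[2], length.out = n_grid),
                 y = seq(yr[1], yr[2], length.out = n_grid))
  }
  Kx <- dnorm(outer(grid$x, points[, 1], "-") / bandwidth)
  Ky <- dnorm(outer(grid$y, points[, 2], "-") / bandwidth)
  z <- (Kx %*% t(Ky)) / (n * bandwidth^2)
  structure(list(x = grid$x, y = grid$y, z = z, bandwidth = bandwidth,
                 cell = (grid$x[2] - grid$x[1]) * (grid$y[2] - grid$y[1])),
            class = "kernel_ud")
}

#' Reference (Silverman-type) bandwidth for a 2-D location sample
#'
#' @param points n x 2 matrix.
#' @return bandwidth in meters.
#' @export
reference_bandwidth <- function(points) {
  points <- matrix(as.numeric(points), ncol = 2)
  n <- nrow(points)
  s <- sqrt(mean(c(var(points[, 1]), var(points[, 2]))))
  if (!is.finite(s) || s <= 0) s <- 1
  s * n^(-1 / 6)
}

#' Home-range isopleth and convex hull
#'
#' The `level` isopleth of a kernel utilization distribution is the
#' smallest-area set of grid cells enclosing `level` of the UD mass
#' (density-threshold rule); it may be multi-part. The convex hull of the
#' locations is the classical alternative.
#'
#' @param ud a [kernel_ud()] surface, or an n x 2 matrix of locations (in
#'   which case `bandwidth` must be given or defaults to the reference
#'   rule).
#' @param level isopleth level in (0, 1), default 0.95.
#' @param bandwidth bandwidth when `ud` is a point matrix.
#' @return list with `isopleth_area` (m^2), `isopleth_polygons` (list of
#'   closed rings), `hull` (closed polygon matrix or NULL for < 3 points),
#'   `hull_area` (m^2), `threshold`, `level`.
#' @export
isopleth_and_hull <- function(ud, level = 0.95, bandwidth = NULL) {
  if (level <= 0 || level >= 1) stop("level must be in (0,1)")
  pts <- NULL
  if (!inherits(ud, "kernel_ud")) {
    pts <- matrix(as.numeric(ud), ncol = 2)
    if (is.null(bandwidth)) bandwidth <- reference_bandwidth(pts)
    ud <- kernel_ud(pts, bandwidth)
  }
  thr <- .ud_threshold(ud, level)
  area <- sum(ud$z >= thr) * ud$cell
  cl <- grDevices::contourLines(ud$x, ud$y, ud$z, levels = thr)
  polys <- lapply(cl, function(c0) {
    m <- cbind(x = c0$x, y = c0$y)
    if (any(m[1, ] != m[nrow(m), ])) m <- rbind(m, m[1, ])
    m
  })
  hull <- NULL; hull_area <- NA_real_
  if (!is.null(pts) && nrow(unique(pts)) >= 3L) {
    h <- grDevices::chull(pts)
    hull <- pts[c(h, h[1]), , drop = FALSE]
    colnames(hull) <- c("x", "y")
    hull_area <- polygon_area(hull)
  }
  list(isopleth_area = area, isopleth_polygons = polys,
       hull = hull, hull_area = hull_area, threshold = thr, level = level)
}

## density threshold enclosing `level` of UD mass on the grid
.ud_threshold <- function(ud, level) {
  dens <- sort(as.numeric(ud$z), decreasing = TRUE)
  mass <- cumsum(dens) * ud$cell
  k <- which(mass >= level)[1]
  if (is.na(k)) k <- length(dens)
  dens[k]
}

#' Shoelace area of a closed polygon
#'
#' @param poly matrix of vertices (closed or open ring).
#' @return absolute enclosed area.
#' @export
polygon_area <- function(poly) {
  poly <- matrix(as.numeric(poly), ncol = 2)
  if (any(poly[1, ] != poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

#' Posterior distribution of home-range shape and area
#'
#' Propagates location uncertainty into home-range estimation by treating
#' the home range as a derived quantity of the location posterior: for each
#' sampled MCMC iteration k, the kernel UD isopleth and convex hull are
#' computed from that iteration's joint draw of all relocation locations,
#' yielding a posterior distribution of home-range area. A plug-in estimate
#' from fixed point estimates (e.g. classical triangulation fits), which
#' ignores location uncertainty, can be supplied for comparison.
#'
#' The bandwidth is computed once from the posterior-median locations and
#' held fixed across iterations, so that variation in the derived areas
#' reflects location uncertainty only.
#'
#' @param fit an `atm_fit` covering the relocations of one individual.
#' @param level isopleth level (default 0.95).
#' @param bandwidth fixed kernel bandwidth; default reference rule on the
#'   posterior-median locations.
#' @param n_mc number of equally spaced MCMC iterations to derive from.
#' @param plugin_points optional n x 2 matrix of fixed location estimates
#'   for the ignore-uncertainty comparison.
#' @return object of class `home_range_posterior`: per-iteration isopleth
#'   and hull areas, their summaries, the bandwidth, and (optionally) the
#'   plug-in areas.
#' @export
home_range_posterior <- function(fit, level = 0.95, bandwidth = NULL,
                                 n_mc = 500L, plugin_points = NULL) {
  nk <- dim(fit$mu_draws)[1]
  M <- dim(fit$mu_draws)[2]
  iters <- unique(round(seq(1L, nk, length.out = min(n_mc, nk))))
  med <- cbind(apply(fit$mu_draws[, , 1, drop = FALSE], 2, median),
               apply(fit$mu_draws[, , 2, drop = FALSE], 2, median))
  if (is.null(bandwidth)) bandwidth <- reference_bandwidth(med)
  iso_area <- hull_area <- numeric(length(iters))
  for (j in seq_along(iters)) {
    pts <- matrix(fit$mu_draws[iters[j], , ], M, 2)
    ih <- isopleth_and_hull(pts, level = level, bandwidth = bandwidth)
    iso_area[j] <- ih$isopleth_area
    hull_area[j] <- if (is.na(ih$hull_area)) 0 else ih$hull_area
  }
  plugin <- NULL
  if (!is.null(plugin_points)) {
    ih <- isopleth_and_hull(matrix(as.numeric(plugin_points), ncol = 2),
                            level = level, bandwidth = bandwidth)
    plugin <- list(isopleth_area = ih$isopleth_area,
                   hull_area = ih$hull_area)
  }
  structure(list(
    iso_area = iso_area, hull_area = hull_area,
    bandwidth = bandwidth, level = level, iterations = iters,
    summary = data.frame(
      quantity = c("isopleth_area", "hull_area"),
      median = c(median(iso_area), median(hull_area)),
      lower95 = c(quantile(iso_area, 0.025), quantile(hull_area, 0.025)),
      upper95 = c(quantile(iso_area, 0.975), quantile(hull_area, 0.975))),
    plugin = plugin),
    class = "home_range_posterior")
}

#' @export
print.home_range_posterior <- function(x, ...) {
  cat(sprintf("Home-range posterior (%d derived iterations, b = %.1f m)\n",
              length(x$iso_area), x$bandwidth))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %s: median %.3g m^2 (95%% CI %.3g - %.3g)\n",
                s$quantity[i], s$median[i], s$lower95[i], s$upper95[i]))
  }
  if (!is.null(x$plugin)) {
    cat(sprintf("  plug-in (uncertainty ignored): isopleth %.3g, hull %.3g m^2\n",
                x$plugin$isopleth_area, x$plugin$hull_area))
  }
  invisible(x)
}
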