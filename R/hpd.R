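#' Highest-posterior-density region from location draws
#'
#' Builds the HPD isopleth used to summarise a location posterior: a
#' Gaussian product-kernel density is estimated from the draws (bandwidths
#' by the normal reference rule), and the density threshold is the largest
#' value such that the draws with density at or above it carry at least
#' `level` of the posterior mass (measured as a fraction of draws). A point
#' is inside the region when its estimated density reaches the threshold.
#'
#' @param draws n x 2 matrix of posterior location draws.
#' @param level probability content of the region, in (0, 1).
#' @param bandwidth optional common kernel bandwidth (m); default is the
#'   normal reference rule per coordinate.
#' @param max_draws subsample cap for the density evaluation (the kernel
#'   sum is quadratic in the number of draws).
#' @return object of class `hpd_region`.
#' @export
hpd_region <- function(draws, level = 0.95, bandwidth = NULL,
                       max_draws = 1000L) {
  if (level <= 0 || level >= 1) stop("level must be in (0,1)")
  draws <- matrix(as.numeric(draws), ncol = 2)
  n <- nrow(draws)
  if (n < 2L) stop("need at least 2 draws")
  if (n > max_draws) {
    idx <- round(seq(1L, n, length.out = max_draws))
    draws <- draws[idx, , drop = FALSE]
    n <- nrow(draws)
  }
  sx <- sd(draws[, 1]); sy <- sd(draws[, 2])
  if (sx == 0 && sy == 0) {
    return(structure(list(draws = draws, level = level, degenerate = TRUE,
                          point = draws[1, ], threshold = Inf,
                          bandwidth = c(0, 0)),
                     class = "hpd_region"))
  }
  if (is.null(bandwidth)) {
    bw <- c(.bw_ref(draws[, 1]), .bw_ref(draws[, 2]))
  } else {
    bw <- rep(bandwidth, length.out = 2)
  }
  bw <- pmax(bw, 1e-9)
  f <- .kde_at(draws, draws, bw)
  ford <- sort(f, decreasing = TRUE)
  thr <- ford[ceiling(level * n)]
  structure(list(draws = draws, level = level, degenerate = FALSE,
                 threshold = thr, bandwidth = bw),
            class = "hpd_region")
}

## normal reference bandwidth, guarded for low-spread samples
.bw_ref <- function(x) {
  n <- length(x)
  s <- min(sd(x), IQR(x) / 1.349)
  if (!is.finite(s) || s <= 0) s <- sd(x)
  1.06 * s * n^(-1 / 5)
}

## product-Gaussian KDE of `pts` evaluated from sample `draws`
.kde_at <- function(pts, draws, bw) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  Kx <- dnorm(outer(pts[, 1], draws[, 1], "-") / bw[1]) / bw[1]
  Ky <- dnorm(outer(pts[, 2], draws[, 2], "-") / bw[2]) / bw[2]
  rowSums(Kx * Ky) / nrow(draws)
}

#' @rdname hpd_region
#' @param region an `hpd_region`.
#' @param point numeric length-2 point (or n x 2 matrix).
#' @param tol matching tolerance (m) used for degenerate (zero-spread)
#'   posteriors.
#' @export
hpd_contains <- function(region, point, tol = 1e-6) {
  pts <- matrix(as.numeric(point), ncol = 2)
  if (isTRUE(region$degenerate)) {
    return(abs(pts[, 1] - region$point[1]) < tol &
             abs(pts[, 2] - region$point[2]) < tol)
  }
  .kde_at(pts, region$draws, region$bandwidth) >= region$threshold
}

#' @rdname hpd_region
#' @param n_grid grid resolution per axis for area integration and contour
#'   extraction.
#' @return `hpd_area`: area of the region in m^2 by grid integration.
#' @export
hpd_area <- function(region, n_grid = 120L) {
  g <- .hpd_grid(region, n_grid)
  sum(g$z >= region$threshold) * g$cell
}

#' @rdname hpd_region
#' @return `hpd_polygon`: list of closed polygon matrices (the isopleth may
#'   be multi-part).
#' @export
hpd_polygon <- function(region, n_grid = 120L) {
  g <- .hpd_grid(region, n_grid)
  cl <- grDevices::contourLines(g$x, g$y, g$z, levels = region$threshold)
  lapply(cl, function(c0) {
    m <- cbind(x = c0$x, y = c0$y)
    if (any(m[1, ] != m[nrow(m), ])) m <- rbind(m, m[1, ])
    m
  })
}

.hpd_grid <- function(region, n_grid) {
  if (isTRUE(region$degenerate)) stop("degenerate posterior has no density grid")
  d <- region$draws; bw <- region$bandwidth
  xr <- range(d[, 1]) + c(-4, 4) * bw[1]
  yr <- range(d[, 2]) + c(-4, 4) * bw[2]
  xs <- seq(xr[1], xr[2], length.out = n_grid)
  ys <- seq(yr[1], yr[2], length.out = n_grid)
  Kx <- dnorm(outer(xs, d[, 1], "-") / bw[1]) / bw[1]
  Ky <- dnorm(outer(ys, d[, 2], "-") / bw[2]) / bw[2]
  z <- Kx %*% t(Ky) / nrow(d)
  list(x = xs, y = ys, z = z, cell = (xs[2] - xs[1]) * (ys[2] - ys[1]))
}
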