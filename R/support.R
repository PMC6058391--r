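#' Union-of-circles support region for an animal location
#'
#' The diffuse prior for each animal location is uniform over the union of
#' circles of radius `r` centred on the stations from which its azimuths
#' were taken: `r` is the maximum distance at which the transmitter can be
#' reliably detected, set from knowledge of the study area.
#'
#' @param stations n x 2 matrix of station coordinates (m).
#' @param radius_r circle radius in meters (> 0).
#' @return object of class `support_region` with the stations, radius and
#'   bounding box.
#' @export
support_region <- function(stations, radius_r) {
  stations <- matrix(as.numeric(stations), ncol = 2)
  if (!is.finite(radius_r) || radius_r <= 0) stop("radius_r must be > 0")
  if (nrow(stations) < 1L) stop("need at least one station")
  structure(list(stations = stations, r = radius_r,
                 bbox = c(xmin = min(stations[, 1]) - radius_r,
                          xmax = max(stations[, 1]) + radius_r,
                          ymin = min(stations[, 2]) - radius_r,
                          ymax = max(stations[, 2]) + radius_r)),
            class = "support_region")
}

#' @rdname support_region
#' @param support a `support_region`.
#' @param points n x 2 matrix (or length-2 vector) of points to test.
#' @return `in_support`: logical vector; a point belongs to the support iff
#'   its distance to the nearest station is at most `r`.
#' @export
in_support <- function(support, points) {
  pts <- matrix(as.numeric(points), ncol = 2)
  r2 <- support$r^2
  st <- support$stations
  out <- rep(FALSE, nrow(pts))
  for (j in seq_len(nrow(st))) {
    out <- out | ((pts[, 1] - st[j, 1])^2 + (pts[, 2] - st[j, 2])^2 <= r2)
  }
  out
}

#' @rdname support_region
#' @param n_grid grid resolution per axis used when more than two circles
#'   require numerical integration.
#' @return `support_area`: area in m^2 (analytic for one or two circles,
#'   deterministic grid integration otherwise).
#' @export
support_area <- function(support, n_grid = 400L) {
  st <- support$stations
  r <- support$r
  ## collapse duplicated stations
  st <- unique(round(st, 9))
  k <- nrow(st)
  if (k == 1L) return(pi * r^2)
  if (k == 2L) {
    d <- sqrt(sum((st[1, ] - st[2, ])^2))
    if (d >= 2 * r) return(2 * pi * r^2)
    lens <- 2 * r^2 * acos(d / (2 * r)) - d / 2 * sqrt(4 * r^2 - d^2)
    return(2 * pi * r^2 - lens)
  }
  bb <- support$bbox
  xs <- seq(bb["xmin"], bb["xmax"], length.out = n_grid)
  ys <- seq(bb["ymin"], bb["ymax"], length.out = n_grid)
  cell <- (xs[2] - xs[1]) * (ys[2] - ys[1])
  inside <- 0L
  for (j in seq_len(nrow(st))) {
    ## accumulate membership without materialising the full grid repeatedly
    dx2 <- (xs - st[j, 1])^2
    dy2 <- (ys - st[j, 2])^2
    m <- outer(dx2, dy2, "+") <= r^2
    if (j == 1L) acc <- m else acc <- acc | m
  }
  sum(acc) * cell
}

#' @rdname support_region
#' @param n number of uniform draws.
#' @return `sample_support`: n x 2 matrix of points uniform on the union of
#'   circles (rejection sampling from the bounding box).
#' @export
sample_support <- function(support, n) {
  bb <- support$bbox
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 64L)
    cand <- cbind(runif(m, bb["xmin"], bb["xmax"]),
                  runif(m, bb["ymin"], bb["ymax"]))
    keep <- cand[in_support(support, cand), , drop = FALSE]
    take <- min(nrow(keep), n - got)
    if (take > 0L) {
      out[(got + 1L):(got + take), ] <- keep[seq_len(take), ]
      got <- got + take
    }
  }
  colnames(out) <- c("x", "y")
  out
}

#' Helper default for the support radius
#'
#' When no study-area knowledge is supplied, a generous default is three
#' times the 95th percentile of pairwise station spacing.
#'
#' @param stations n x 2 matrix of all station coordinates.
#' @return radius in meters.
#' @export
default_radius <- function(stations) {
  stations <- matrix(as.numeric(stations), ncol = 2)
  if (nrow(stations) < 2L) stop("need >= 2 stations to derive a default radius")
  3 * as.numeric(quantile(dist(stations), 0.95))
}
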