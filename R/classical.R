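#' Component-wise average of azimuth intersections
#'
#' The field's simple fallback estimator: intersect every pair of bearings
#' (forward-ray semantics) and average the intersection points
#' component-wise. Pairs that do not cross are dropped; optionally the
#' infinite-line intersections are used when no forward pair crosses.
#'
#' @param stations n x 2 matrix of observer coordinates (m).
#' @param bearings n bearings in radians (mathematical convention).
#' @param fallback_to_lines if no forward-ray pair intersects, fall back to
#'   line intersections.
#' @return length-2 estimate, or `NULL` when no pair intersects at all.
#' @export
intersection_average <- function(stations, bearings, fallback_to_lines = TRUE) {
  stations <- matrix(as.numeric(stations), ncol = 2)
  n <- nrow(stations)
  if (n < 2L || length(bearings) != n) {
    stop("need >= 2 azimuths with matching stations")
  }
  pair_points <- function(rays) {
    pts <- list()
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        if (all(stations[i, ] == stations[j, ])) next
        p <- ray_intersection(stations[i, ], bearings[i],
                              stations[j, ], bearings[j], rays = rays)
        if (!is.null(p)) pts[[length(pts) + 1L]] <- p
      }
    }
    pts
  }
  pts <- pair_points(TRUE)
  if (!length(pts) && fallback_to_lines) pts <- pair_points(FALSE)
  if (!length(pts)) return(NULL)
  colMeans(do.call(rbind, pts))
}

## Best & Fisher style inverse of A(kappa) = I1/I0: estimate concentration
## from a mean resultant length.
.a1inv <- function(R) {
  if (R >= 1) return(Inf)
  if (R < 0.53) {
    2 * R + R^3 + 5 * R^5 / 6
  } else if (R < 0.85) {
    -0.4 + 1.39 * R + 0.43 / (1 - R)
  } else {
    1 / (R^3 - 4 * R^2 + 3 * R)
  }
}

.psi_weight <- function(t, method, c) {
  ## psi(t)/t weights; 1 at t = 0
  w <- rep(1, length(t))
  if (method == "huber") {
    big <- abs(t) > c
    w[big] <- c / abs(t[big])
  } else if (method == "andrews") {
    nz <- abs(t) > 1e-12
    w[nz] <- ifelse(abs(t[nz]) <= c * pi, sin(t[nz] / c) / (t[nz] / c), 0)
  }
  w
}

#' Triangulate a location from two or more azimuths
#'
#' Classical triangulation by maximising the von Mises bearing likelihood,
#' i.e. minimising `sum_i w_i (1 - cos(theta_i - theta_tilde_i(mu)))` where
#' `theta_tilde_i` is the expected bearing from station i. Four methods:
#'
#' * `"mle-fixed-point"`: Lenth-style iteratively reweighted perpendicular
#'   line intersection (Fisher scoring); fixed points are exact roots of
#'   the score equations.
#' * `"huber"`, `"andrews"`: M-estimators that additionally downweight
#'   outlying bearings through `psi(t)/t` with standardized residuals
#'   `t = sqrt(kappa_hat) * (theta - theta_tilde)`; the concentration is
#'   re-estimated each iteration from the mean resultant length of the
#'   bearing residuals.
#' * `"mle-quasi-newton"`: the same objective handed to a quasi-Newton
#'   optimizer (BFGS with finite-difference gradients), the approach Lenth
#'   recommended against; retained as a comparator because it is what some
#'   legacy software uses, and it fails more often.
#'
#' Failures (singular geometry, divergence, iteration cap) are returned as
#' a fit with `converged = FALSE` rather than raised, so that benchmark
#' success rates can be tabulated.
#'
#' @param stations n x 2 matrix of observer coordinates (m).
#' @param bearings n observed bearings, radians, mathematical convention.
#' @param method one of `"mle-fixed-point"`, `"mle-quasi-newton"`,
#'   `"huber"`, `"andrews"`, `"intersection-average"`.
#' @param tuning_c M-estimator tuning constant (default 1.5).
#' @param init starting point; default is the intersection average.
#' @param tol convergence tolerance on the update step (m).
#' @param max_iter iteration cap.
#' @return an object of class `triangulation_fit`: list with `estimate`,
#'   `covariance` (2 x 2, `NA` when unavailable), `cov_ok`, `converged`,
#'   `n_iterations`, `method`, `kappa_hat`.
#' @export
triangulate <- function(stations, bearings,
                        method = c("mle-fixed-point", "mle-quasi-newton",
                                   "huber", "andrews", "intersection-average"),
                        tuning_c = 1.5, init = NULL,
                        tol = 1e-8, max_iter = 100L) {
  method <- match.arg(method)
  stations <- matrix(as.numeric(stations), ncol = 2)
  n <- nrow(stations)
  if (n < 2L || length(bearings) != n) {
    stop("need >= 2 azimuths with matching stations")
  }
  fail <- function(est = c(NA_real_, NA_real_), iter = 0L) {
    structure(list(estimate = est,
                   covariance = matrix(NA_real_, 2, 2),
                   cov_ok = FALSE, converged = FALSE,
                   n_iterations = iter, method = method,
                   kappa_hat = NA_real_),
              class = "triangulation_fit")
  }

  spread <- max(dist(stations))
  if (spread == 0) return(fail())

  if (is.null(init)) {
    init <- intersection_average(stations, bearings, fallback_to_lines = TRUE)
    if (is.null(init)) {
      ## all bearings (anti)parallel: start from the station centroid pushed
      ## along the mean bearing direction
      u <- c(mean(cos(bearings)), mean(sin(bearings)))
      nu <- sqrt(sum(u^2))
      if (nu < 1e-12) u <- c(cos(bearings[1]), sin(bearings[1])) else u <- u / nu
      init <- colMeans(stations) + u * spread
    }
  }

  if (method == "intersection-average") {
    est <- intersection_average(stations, bearings, fallback_to_lines = TRUE)
    if (is.null(est)) return(fail())
    out <- fail(est)
    out$converged <- TRUE
    return(out)
  }

  objective <- function(mu) {
    tt <- expected_bearing(matrix(mu, 1, 2), stations)
    sum(1 - cos(bearings - tt))
  }

  if (method == "mle-quasi-newton") {
    opt <- tryCatch(
      optim(init, objective, method = "BFGS",
            control = list(reltol = 1e-14, maxit = 500)),
      error = function(e) NULL)
    if (is.null(opt)) return(fail())
    est <- opt$par
    if (opt$convergence != 0 ||
        sqrt(sum((est - colMeans(stations))^2)) > 10 * (spread + 1)) {
      f <- fail(est, iter = 1L)
      return(f)
    }
    info <- .triang_information(stations, bearings, est)
    return(.finish_fit(est, info, method, iter = opt$counts[["function"]],
                       converged = TRUE, n = n))
  }

  ## Fisher-scoring / IRLS schemes with backtracking damping
  mu <- init
  converged <- FALSE
  iter <- 0L
  kap <- NA_real_
  wobj <- function(mu, w) {
    tt <- expected_bearing(matrix(mu, 1, 2), stations)
    sum(w * (1 - cos(bearings - tt)))
  }
  max_step <- 10 * (spread + sqrt(sum((init - colMeans(stations))^2)) + 1)
  repeat {
    iter <- iter + 1L
    dx <- mu[1] - stations[, 1]
    dy <- mu[2] - stations[, 2]
    d <- sqrt(dx^2 + dy^2)
    if (any(d < 1e-9)) return(fail(mu, iter))
    tt <- atan2(dy, dx)
    res <- wrap_radians(bearings - tt)
    Rbar <- sqrt(mean(cos(res))^2 + mean(sin(res))^2)
    kap <- .a1inv(Rbar)
    w <- rep(1, n)
    if (method %in% c("huber", "andrews")) {
      kstd <- if (is.finite(kap)) kap else 1e12
      tstd <- res * sqrt(kstd)
      w <- .psi_weight(tstd, method, tuning_c)
    }
    sn <- -sin(tt); cs <- cos(tt)
    wd2 <- w / d^2
    A <- matrix(c(sum(wd2 * sn * sn), sum(wd2 * sn * cs),
                  sum(wd2 * sn * cs), sum(wd2 * cs * cs)), 2, 2)
    g <- c(sum(w * sin(res) / d * sn), sum(w * sin(res) / d * cs))
    detA <- A[1, 1] * A[2, 2] - A[1, 2]^2
    if (!is.finite(detA) || detA <= 1e-14 * max(abs(A))^2 ||
        sum(w > 1e-8) < 2) {
      return(fail(mu, iter))
    }
    step <- tryCatch(solve(A, g), error = function(e) NULL)
    if (is.null(step)) return(fail(mu, iter))
    if (!all(is.finite(step))) return(fail(mu, iter))
    if (sqrt(sum(step^2)) > max_step) return(fail(mu, iter))  # divergence
    ## damp the step until the (frozen-weight) objective does not increase
    f0 <- wobj(mu, w)
    lambda <- 1
    for (half in 1:25) {
      cand <- mu + lambda * step
      if (wobj(cand, w) <= f0 + 1e-14) break
      lambda <- lambda / 2
    }
    mu <- mu + lambda * step
    if (sqrt(sum((lambda * step)^2)) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  info <- .triang_information(stations, bearings, mu,
                              weights = if (method %in% c("huber", "andrews")) w else NULL)
  .finish_fit(mu, info, method, iter, converged, n)
}

## expected information for the location at kappa_hat, up to weights
.triang_information <- function(stations, bearings, mu, weights = NULL) {
  dx <- mu[1] - stations[, 1]
  dy <- mu[2] - stations[, 2]
  d2 <- dx^2 + dy^2
  tt <- atan2(dy, dx)
  res <- wrap_radians(bearings - tt)
  Rbar <- sqrt(mean(cos(res))^2 + mean(sin(res))^2)
  kap <- .a1inv(Rbar)
  w <- if (is.null(weights)) rep(1, length(bearings)) else weights
  sn <- -sin(tt); cs <- cos(tt)
  H <- matrix(c(sum(w * sn * sn / d2), sum(w * sn * cs / d2),
                sum(w * sn * cs / d2), sum(w * cs * cs / d2)), 2, 2)
  list(H = H, kappa = kap, n = length(bearings))
}

.finish_fit <- function(est, info, method, iter, converged, n) {
  cov_ok <- FALSE
  covm <- matrix(NA_real_, 2, 2)
  if (converged && n >= 3L && is.finite(info$kappa) && info$kappa > 0) {
    detH <- info$H[1, 1] * info$H[2, 2] - info$H[1, 2]^2
    if (is.finite(detH) && detH > 0) {
      covm <- solve(info$kappa * info$H)
      covm <- (covm + t(covm)) / 2
      cov_ok <- all(is.finite(covm)) && all(diag(covm) > 0)
    }
  }
  structure(list(estimate = as.numeric(est), covariance = covm,
                 cov_ok = cov_ok, converged = converged,
                 n_iterations = as.integer(iter), method = method,
                 kappa_hat = info$kappa),
            class = "triangulation_fit")
}

#' @export
print.triangulation_fit <- function(x, ...) {
  cat("Triangulation fit (", x$method, ")\n", sep = "")
  if (x$converged) {
    cat(sprintf("  estimate: (%.2f, %.2f) m after %d iterations\n",
                x$estimate[1], x$estimate[2], x$n_iterations))
    if (x$cov_ok) {
      cat(sprintf("  kappa-hat %.1f; location SDs (%.1f, %.1f) m\n",
                  x$kappa_hat, sqrt(x$covariance[1, 1]),
                  sqrt(x$covariance[2, 2])))
    } else {
      cat("  covariance unavailable\n")
    }
  } else {
    cat("  did not converge\n")
  }
  invisible(x)
}

#' Asymptotic confidence ellipse for a triangulation fit
#'
#' The set `{u : (u - mu)' Sigma^-1 (u - mu) <= chisq_2(level)}` from the
#' asymptotic-normality approximation; its area is
#' `pi * chisq_2(level) * sqrt(det Sigma)`.
#'
#' @param fit a converged `triangulation_fit` with a valid covariance, or a
#'   list with `estimate` and `covariance`.
#' @param level coverage probability in (0, 1).
#' @return object of class `confidence_ellipse` with `center`, `semi_axes`,
#'   `orientation` (radians), `level`, `area` (m^2), and the covariance.
#' @export
confidence_ellipse <- function(fit, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0,1)")
  S <- fit$covariance
  if (any(!is.finite(S))) stop("covariance unavailable")
  dS <- det(S)
  if (dS <= 0) stop("singular covariance")
  q <- qchisq(level, df = 2)
  e <- eigen(S, symmetric = TRUE)
  structure(list(center = fit$estimate,
                 semi_axes = sqrt(q * e$values),
                 orientation = atan2(e$vectors[2, 1], e$vectors[1, 1]),
                 level = level,
                 area = pi * q * sqrt(dS),
                 covariance = S),
            class = "confidence_ellipse")
}

#' @rdname confidence_ellipse
#' @param ellipse a `confidence_ellipse`.
#' @param point numeric length-2 point to test.
#' @export
ellipse_contains <- function(ellipse, point) {
  dv <- as.numeric(point) - ellipse$center
  q <- drop(t(dv) %*% solve(ellipse$covariance) %*% dv)
  q <= qchisq(ellipse$level, df = 2)
}

#' @rdname confidence_ellipse
#' @param n_vertices number of polygon vertices.
#' @export
ellipse_polygon <- function(ellipse, n_vertices = 100L) {
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1L)
  a <- ellipse$semi_axes[1]; b <- ellipse$semi_axes[2]
  ro <- ellipse$orientation
  x <- a * cos(ang); y <- b * sin(ang)
  cbind(x = ellipse$center[1] + x * cos(ro) - y * sin(ro),
        y = ellipse$center[2] + x * sin(ro) + y * cos(ro))
}
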