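#' Wrap an angle to (-pi, pi]
#'
#' All internal angular arithmetic uses mathematical convention: radians,
#' measured counterclockwise from the +x (east) axis, wrapped to `(-pi, pi]`.
#'
#' @param theta numeric vector of angles in radians.
#' @return numeric vector wrapped to `(-pi, pi]`.
#' @export
#' @examples
#' wrap_radians(3 * pi)   # pi
#' wrap_radians(-pi)      # pi
wrap_radians <- function(theta) {
  if (!all(is.finite(theta))) stop("non-finite angle")
  theta - 2 * pi * ceiling((theta - pi) / (2 * pi))
}

#' Convert compass azimuths (degrees) to mathematical bearings (radians)
#'
#' Field azimuths are recorded as compass degrees, clockwise from north
#' (0 = north, 90 = east). Internally the package uses radians
#' counterclockwise from east, so `rad = wrap(pi/2 - deg * pi/180)`.
#'
#' @param deg numeric vector of compass azimuths in degrees.
#' @return mathematical bearings in radians, wrapped to `(-pi, pi]`.
#' @export
#' @examples
#' compass_to_math(0)    # pi/2  (north)
#' compass_to_math(90)   # 0    (east)
compass_to_math <- function(deg) {
  if (!all(is.finite(deg))) stop("non-finite azimuth")
  wrap_radians(pi / 2 - deg * pi / 180)
}

#' @rdname compass_to_math
#' @param theta mathematical bearings in radians.
#' @export
math_to_compass <- function(theta) {
  if (!all(is.finite(theta))) stop("non-finite angle")
  (90 - theta * 180 / pi) %% 360
}

#' Expected bearing from a station toward an animal location
#'
#' The trigonometric link between a planar animal location and the noise-free
#' bearing observed at a station: the quadrant-aware inverse tangent of the
#' displacement vector `mu - z`.
#'
#' @param mu animal location, numeric length-2 `(x, y)` or n x 2 matrix.
#' @param z station location, same shape as `mu` (recycled if length 2).
#' @return bearing(s) in radians in `(-pi, pi]`.
#' @export
expected_bearing <- function(mu, z) {
  mu <- matrix(as.numeric(mu), ncol = 2)
  z <- matrix(as.numeric(z), ncol = 2)
  if (nrow(z) == 1L && nrow(mu) > 1L) z <- z[rep(1L, nrow(mu)), , drop = FALSE]
  if (nrow(mu) == 1L && nrow(z) > 1L) mu <- mu[rep(1L, nrow(z)), , drop = FALSE]
  dx <- mu[, 1] - z[, 1]
  dy <- mu[, 2] - z[, 2]
  if (any(dx == 0 & dy == 0)) {
    stop("degenerate geometry: animal location coincides with a station")
  }
  atan2(dy, dx)
}

#' Von Mises log-density
#'
#' Circular analogue of the normal distribution; the azimuthal observation
#' model. Log-density is `kappa * cos(theta - mu) - log(2 pi I0(kappa))`
#' using the exponentially scaled Bessel function for numerical stability
#' at large concentration. `kappa = 0` is the circular uniform.
#'
#' @param theta angles (radians).
#' @param mu mean direction (radians).
#' @param kappa concentration (dimensionless, `>= 0`); larger values mean
#'   less angular spread.
#' @param log logical; return the log-density (default) or the density.
#' @return log-density values.
#' @export
dvonmises <- function(theta, mu, kappa, log = TRUE) {
  if (any(kappa < 0)) stop("kappa must be >= 0")
  ld <- kappa * cos(theta - mu) - log(2 * pi) - log_bessel_i0(kappa)
  if (log) ld else exp(ld)
}

#' Logarithm of the modified Bessel function I0
#'
#' `log(besselI(kappa, 0))` computed stably for any concentration: the
#' exponentially scaled Bessel function below 1e5, the uniform asymptotic
#' expansion above (where R's Bessel routines lose precision).
#'
#' @param kappa non-negative argument (vectorised).
#' @return `log I0(kappa)`.
#' @export
log_bessel_i0 <- function(kappa) {
  out <- numeric(length(kappa))
  small <- kappa < 1e5
  if (any(small)) {
    k <- kappa[small]
    out[small] <- log(besselI(k, 0, expon.scaled = TRUE)) + k
  }
  if (any(!small)) {
    k <- kappa[!small]
    out[!small] <- k - 0.5 * log(2 * pi * k) +
      log1p(1 / (8 * k) + 9 / (128 * k^2))
  }
  out
}

#' @rdname dvonmises
#' @param n number of draws.
#' @details `rvonmises` uses the Best and Fisher (1979) wrapped-Cauchy
#'   rejection sampler, drawing through R's RNG stream so results are
#'   reproducible under `set.seed()`.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (length(kappa) == 1L) kappa <- rep(kappa, n)
  if (length(mu) == 1L) mu <- rep(mu, n)
  if (any(kappa < 0)) stop("kappa must be >= 0")
  out <- numeric(n)
  unif <- kappa < 1e-10
  out[unif] <- runif(sum(unif), -pi, pi)
  todo <- which(!unif)
  if (length(todo)) {
    k <- kappa[todo]
    a <- 1 + sqrt(1 + 4 * k^2)
    b <- (a - sqrt(2 * a)) / (2 * k)
    r <- (1 + b^2) / (2 * b)
    res <- rep(NA_real_, length(todo))
    pending <- seq_along(todo)
    while (length(pending)) {
      m <- length(pending)
      u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
      z <- cos(pi * u1)
      f <- (1 + r[pending] * z) / (r[pending] + z)
      c0 <- k[pending] * (r[pending] - f)
      ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
      if (any(ok)) {
        idx <- pending[ok]
        res[idx] <- sign(u3[ok] - 0.5) * acos(f[ok])
      }
      pending <- pending[!ok]
    }
    out[todo] <- res
  }
  wrap_radians(out + mu)
}

#' Intersection of two bearing rays
#'
#' Finds the point where two bearings cross. With `rays = TRUE` (the
#' default) each bearing is a forward ray -- it points from the station
#' toward the animal -- and an intersection only counts when it lies
#' strictly forward along both bearings. With `rays = FALSE` the infinite
#' lines are intersected instead.
#'
#' @param z1,z2 station coordinates, numeric length 2.
#' @param b1,b2 bearings in radians (mathematical convention).
#' @param rays logical; forward-ray semantics (default) or full lines.
#' @return numeric length-2 intersection point, or `NULL` when the rays do
#'   not cross (parallel, antiparallel, or crossing behind a station).
#' @export
ray_intersection <- function(z1, b1, z2, b2, rays = TRUE) {
  z1 <- as.numeric(z1); z2 <- as.numeric(z2)
  if (all(z1 == z2)) stop("coincident stations")
  u1 <- c(cos(b1), sin(b1))
  u2 <- c(cos(b2), sin(b2))
  det <- u1[1] * u2[2] - u1[2] * u2[1]
  if (abs(det) < 1e-12) return(NULL)
  w <- z2 - z1
  t1 <- (w[1] * u2[2] - w[2] * u2[1]) / det
  t2 <- (w[1] * u1[2] - w[2] * u1[1]) / det
  if (rays && (t1 <= 1e-12 || t2 <= 1e-12)) return(NULL)
  z1 + t1 * u1
}
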