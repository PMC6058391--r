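#' Describe a radio-telemetry simulation scenario
#'
#' A scenario fixes the observer-placement design, the number of azimuths
#' per relocation, the true bearing concentration, the number of simulated
#' relocations, and the observer-to-animal distance distribution.
#'
#' Designs:
#' * `"random"`: each station sits at an independent uniform bearing from
#'   the animal, at a sampled distance.
#' * `"encircle"`: the first station is placed as in `random`; each later
#'   station's bearing (seen from the animal) advances by a uniform 30-60
#'   degree step (counterclockwise), distance resampled each time, so the
#'   stations end up surrounding the animal.
#' * `"road"`: stations are constrained to a random line (a road). The
#'   line's orientation is uniform, its offset from the animal is drawn
#'   from the distance distribution, and stations are spread at ordered
#'   positions spanning one offset to either side of the foot of the
#'   perpendicular, which limits angular diversity.
#'
#' @param design `"random"`, `"encircle"` or `"road"`.
#' @param n_theta azimuths per relocation.
#' @param kappa_true true von Mises concentration.
#' @param n_locations number of simulated relocations.
#' @param distance_sampler function(n) returning n observer distances (m);
#'   default uniform on 100-1000 m, a stand-in for field-estimated
#'   observer-animal distances.
#' @return a `design_scenario` list.
#' @export
design_scenario <- function(design = c("random", "encircle", "road"),
                            n_theta = 3L, kappa_true = 100,
                            n_locations = 600L,
                            distance_sampler = function(n) runif(n, 100, 1000)) {
  design <- match.arg(design)
  stopifnot(n_theta >= 1L, kappa_true > 0, n_locations >= 1L)
  structure(list(design = design, n_theta = as.integer(n_theta),
                 kappa_true = kappa_true,
                 n_locations = as.integer(n_locations),
                 distance_sampler = distance_sampler),
            class = "design_scenario")
}

#' Generate observer stations for one relocation
#'
#' @param truth length-2 true animal location.
#' @param scenario a [design_scenario()] (or the design string, with
#'   `n_theta` and `distance_sampler` given separately).
#' @param n_theta,distance_sampler used when `scenario` is a string.
#' @return n_theta x 2 matrix of station coordinates.
#' @export
generate_design <- function(truth, scenario, n_theta = 3L,
                            distance_sampler = function(n) runif(n, 100, 1000)) {
  if (inherits(scenario, "design_scenario")) {
    design <- scenario$design
    n_theta <- scenario$n_theta
    distance_sampler <- scenario$distance_sampler
  } else {
    design <- match.arg(scenario, c("random", "encircle", "road"))
  }
  truth <- as.numeric(truth)
  if (design == "random") {
    phi <- runif(n_theta, -pi, pi)
    d <- distance_sampler(n_theta)
    st <- cbind(truth[1] + d * cos(phi), truth[2] + d * sin(phi))
  } else if (design == "encircle") {
    phi1 <- runif(1, -pi, pi)
    steps <- if (n_theta > 1L) runif(n_theta - 1L, pi / 6, pi / 3) else numeric()
    phi <- phi1 + c(0, cumsum(steps))  # counterclockwise
    d <- distance_sampler(n_theta)
    st <- cbind(truth[1] + d * cos(phi), truth[2] + d * sin(phi))
  } else {
    psi <- runif(1, -pi, pi)            # road orientation
    h <- distance_sampler(1L)           # perpendicular offset to the road
    foot <- truth + h * c(cos(psi + pi / 2), sin(psi + pi / 2))
    tpos <- if (n_theta == 1L) 0 else seq(-h, h, length.out = n_theta)
    st <- cbind(foot[1] + tpos * cos(psi), foot[2] + tpos * sin(psi))
  }
  colnames(st) <- c("x", "y")
  st
}

#' Simulate azimuth observations for one relocation
#'
#' One bearing per station, drawn von Mises around the true
#' station-to-animal direction.
#'
#' @param truth length-2 true animal location.
#' @param stations n x 2 station matrix.
#' @param kappa_true von Mises concentration of the bearing errors.
#' @return data.frame with columns `x`, `y`, `theta` (math radians) and
#'   `azimuth` (compass degrees).
#' @export
simulate_relocation <- function(truth, stations, kappa_true) {
  stations <- matrix(as.numeric(stations), ncol = 2)
  tt <- expected_bearing(matrix(as.numeric(truth), 1, 2), stations)
  th <- rvonmises(nrow(stations), tt, kappa_true)
  data.frame(x = stations[, 1], y = stations[, 2],
             theta = th, azimuth = math_to_compass(th))
}

#' Simulate a full scenario of relocations
#'
#' @param scenario a [design_scenario()].
#' @return list with `obs` (azimuth table with `relocation` ids) and
#'   `truth` (n_locations x 2 matrix; every true location is at the
#'   origin of its own local frame -- the estimators are translation
#'   equivariant, so the frame choice is immaterial).
#' @export
simulate_scenario <- function(scenario) {
  n <- scenario$n_locations
  truth <- matrix(0, n, 2)
  obs <- vector("list", n)
  for (i in seq_len(n)) {
    st <- generate_design(truth[i, ], scenario)
    o <- simulate_relocation(truth[i, ], st, scenario$kappa_true)
    o$relocation <- i
    obs[[i]] <- o
  }
  list(obs = do.call(rbind, obs), truth = truth)
}

#' Benchmark estimators over study-design scenarios
#'
#' For each scenario, simulates relocations, fits the requested estimators,
#' and tabulates the number of successful estimates (`n_hat`), the median
#' Euclidean error of the point estimates (`d_median`, m, over successes),
#' and the fraction of 95% uncertainty regions (confidence ellipses for the
#' classical estimators, HPD isopleths for the ATM) containing the true
#' location (`coverage`, out of the successful fits with a region).
#'
#' @param scenarios list of [design_scenario()] objects (a single scenario
#'   is accepted).
#' @param estimators subset of `c("intersection-average", "mle-fixed-point",
#'   "mle-quasi-newton", "huber", "andrews", "atm")`.
#' @param radius_r ATM support radius (m); the default, 1000 m, is the
#'   upper bound of the default observer-distance distribution, i.e. the
#'   maximum reliable detection distance of the simulated study.
#' @param mcmc [mcmc_control()] for the ATM fits (shared-concentration
#'   model, fit jointly per scenario).
#' @param level coverage level for the uncertainty regions.
#' @param seed optional seed set before each scenario block.
#' @return data.frame with one row per scenario x estimator.
#' @export
run_benchmark <- function(scenarios,
                          estimators = c("intersection-average",
                                         "mle-fixed-point",
                                         "mle-quasi-newton",
                                         "huber", "andrews", "atm"),
                          radius_r = 1000, mcmc = mcmc_control(4000L),
                          level = 0.95, seed = NULL) {
  if (inherits(scenarios, "design_scenario")) scenarios <- list(scenarios)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (sc in scenarios) {
    sim <- simulate_scenario(sc)
    n <- sc$n_locations
    split_obs <- split(sim$obs, sim$obs$relocation)
    split_obs <- split_obs[order(as.integer(names(split_obs)))]

    for (est in estimators) {
      if (est == "atm") {
        fit <- fit_atm(sim$obs, radius_r = radius_r,
                       kappa_model = kappa_homogeneous(), mcmc = mcmc)
        errs <- numeric(n); cov <- logical(n)
        for (i in seq_len(n)) {
          dr <- location_draws(fit, i)
          pm <- apply(dr, 2, median)
          errs[i] <- sqrt(sum((pm - sim$truth[i, ])^2))
          reg <- hpd_region(dr, level = level)
          cov[i] <- hpd_contains(reg, sim$truth[i, ])
        }
        rows[[length(rows) + 1L]] <- data.frame(
          design = sc$design, kappa = sc$kappa_true, n_theta = sc$n_theta,
          estimator = est, n_hat = n, d_median = median(errs),
          coverage = mean(cov))
      } else {
        ok <- logical(n); errs <- rep(NA_real_, n); cv <- rep(NA, n)
        for (i in seq_len(n)) {
          o <- split_obs[[i]]
          f <- triangulate(cbind(o$x, o$y), o$theta, method = est)
          if (isTRUE(f$converged) && all(is.finite(f$estimate))) {
            ok[i] <- TRUE
            errs[i] <- sqrt(sum((f$estimate - sim$truth[i, ])^2))
            if (f$cov_ok) {
              el <- confidence_ellipse(f, level)
              cv[i] <- ellipse_contains(el, sim$truth[i, ])
            }
          }
        }
        rows[[length(rows) + 1L]] <- data.frame(
          design = sc$design, kappa = sc$kappa_true, n_theta = sc$n_theta,
          estimator = est, n_hat = sum(ok),
          d_median = median(errs[ok]),
          coverage = if (any(!is.na(cv))) mean(cv, na.rm = TRUE) else NA_real_)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
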