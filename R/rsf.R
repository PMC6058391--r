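#' Availability region for resource selection
#'
#' Availability is assumed spatially uniform within either the study-area
#' region (the raster extent, first-order selection) or the convex hull of
#' a set of locations (second-order selection).
#'
#' @param raster a [cov_raster()] (for `"extent"` availability).
#' @param hull_points n x 2 matrix whose convex hull defines the region
#'   (for `"hull"` availability).
#' @return object of class `availability`.
#' @export
availability_extent <- function(raster) {
  structure(list(type = "extent", extent = raster_extent(raster)),
            class = "availability")
}

#' @rdname availability_extent
#' @export
availability_hull <- function(hull_points) {
  pts <- matrix(as.numeric(hull_points), ncol = 2)
  if (nrow(unique(pts)) < 3L) stop("need >= 3 distinct points for a hull")
  h <- grDevices::chull(pts)
  poly <- pts[c(h, h[1]), , drop = FALSE]
  structure(list(type = "hull", polygon = poly), class = "availability")
}

.in_availability <- function(avail, points) {
  pts <- matrix(as.numeric(points), ncol = 2)
  if (is.null(avail)) return(rep(TRUE, nrow(pts)))
  if (avail$type == "extent") {
    e <- avail$extent
    pts[, 1] >= e["xmin"] & pts[, 1] <= e["xmax"] &
      pts[, 2] >= e["ymin"] & pts[, 2] <= e["ymax"]
  } else {
    in_polygon(avail$polygon, pts)
  }
}

#' Point-in-polygon test (even-odd rule)
#'
#' @param poly polygon vertex matrix (closed or open ring).
#' @param points n x 2 matrix of query points.
#' @return logical vector.
#' @export
in_polygon <- function(poly, points) {
  poly <- matrix(as.numeric(poly), ncol = 2)
  if (all(poly[1, ] == poly[nrow(poly), ])) poly <- poly[-nrow(poly), , drop = FALSE]
  pts <- matrix(as.numeric(points), ncol = 2)
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

## Preprocess a raster + availability into the pieces the RSF code uses:
## standardized design matrix over available cells, cell centers, and the
## standardization (continuous layers centered/scaled over availability).
.rsf_prep <- function(raster, availability = NULL) {
  cs <- raster$cellsize
  cx <- raster$origin[1] + (seq_len(raster$nx) - 0.5) * cs
  cy <- raster$origin[2] + (seq_len(raster$ny) - 0.5) * cs
  centers <- cbind(rep(cx, times = raster$ny), rep(cy, each = raster$nx))
  ok <- .in_availability(availability, centers)
  if (!any(ok)) stop("availability region contains no raster cells")
  p <- length(raster$layers)
  Xall <- matrix(NA_real_, nrow(centers), p,
                 dimnames = list(NULL, names(raster$layers)))
  for (l in seq_len(p)) Xall[, l] <- as.numeric(raster$layers[[l]])
  standardize <- vector("list", p)
  names(standardize) <- names(raster$layers)
  for (l in seq_len(p)) {
    v <- Xall[ok, l]
    is_cat <- all(v %in% c(0, 1))
    if (is_cat) {
      standardize[[l]] <- c(center = 0, scale = 1)
    } else {
      sc <- sd(v)
      if (!is.finite(sc) || sc == 0) {
        warning(sprintf("covariate '%s' has zero variance within availability; coefficient unidentifiable",
                        names(raster$layers)[l]))
        sc <- 1
      }
      standardize[[l]] <- c(center = mean(v), scale = sc)
      Xall[, l] <- (Xall[, l] - mean(v)) / sc
    }
  }
  list(cellX = Xall[ok, , drop = FALSE], centers = centers, ok = ok,
       Xall = Xall, cell_area = cs^2, standardize = standardize,
       availability = availability)
}

## standardized covariate design rows at arbitrary points (NA outside grid)
.raster_design <- function(raster, points, standardize) {
  pts <- matrix(as.numeric(points), ncol = 2)
  p <- length(raster$layers)
  X <- matrix(NA_real_, nrow(pts), p)
  for (l in seq_len(p)) {
    v <- raster_values(raster, pts, l)
    st <- standardize[[l]]
    X[, l] <- (v - st["center"]) / st["scale"]
  }
  X
}

.rsf_loglik_cells <- function(gamma, xloc, cellX, cell_area) {
  lp <- drop(cellX %*% gamma)
  mx <- max(lp)
  sum(xloc %*% gamma) -
    nrow(xloc) * (mx + log(sum(exp(lp - mx))) + log(cell_area))
}

#' Sample locations from an inhomogeneous point process on a raster
#'
#' Draws cells with probability proportional to `exp(x' gamma)` (times the
#' cell area) restricted to the availability region, then uniformly within
#' the chosen cell. Covariates are standardized over the availability
#' region, so `gamma` is on the standardized scale.
#'
#' @param gamma selection coefficient vector (one per raster layer).
#' @param raster a [cov_raster()].
#' @param availability an availability region (default: raster extent).
#' @param n number of locations.
#' @return n x 2 matrix of locations.
#' @export
sample_ipp_locations <- function(gamma, raster, n, availability = NULL) {
  prep <- .rsf_prep(raster, availability)
  lp <- drop(prep$cellX %*% gamma)
  w <- exp(lp - max(lp))
  idx <- sample.int(nrow(prep$cellX), n, replace = TRUE, prob = w)
  ctr <- prep$centers[prep$ok, , drop = FALSE][idx, , drop = FALSE]
  cs <- raster$cellsize
  pts <- ctr + cbind(runif(n, -cs / 2, cs / 2), runif(n, -cs / 2, cs / 2))
  if (!is.null(availability) && availability$type == "hull") {
    ## re-draw any point that fell in a cell corner outside the hull
    bad <- which(!.in_availability(availability, pts))
    while (length(bad)) {
      pts[bad, ] <- prep$centers[prep$ok, , drop = FALSE][
        sample.int(nrow(prep$cellX), length(bad), replace = TRUE, prob = w), ,
        drop = FALSE] +
        cbind(runif(length(bad), -cs / 2, cs / 2),
              runif(length(bad), -cs / 2, cs / 2))
      bad <- bad[!.in_availability(availability, pts[bad, , drop = FALSE])]
    }
  }
  colnames(pts) <- c("x", "y")
  pts
}

#' Resource-selection log-likelihood (weighted distribution)
#'
#' The inhomogeneous point-process log-likelihood under uniform
#' availability, with the normalizing integral approximated by the
#' midpoint cell sum at raster resolution:
#' `sum_i x(mu_i)' gamma - n log( sum_cells exp(x' gamma) * cell_area )`.
#'
#' @param gamma coefficient vector.
#' @param locations n x 2 matrix of use locations (must lie inside the
#'   availability region).
#' @param raster a [cov_raster()].
#' @param availability availability region (default raster extent).
#' @return scalar log-likelihood.
#' @export
rsf_log_likelihood <- function(gamma, locations, raster, availability = NULL) {
  prep <- .rsf_prep(raster, availability)
  pts <- matrix(as.numeric(locations), ncol = 2)
  if (!all(.in_availability(availability, pts))) {
    stop("location(s) outside the availability region")
  }
  X <- .raster_design(raster, pts, prep$standardize)
  if (anyNA(X)) stop("location(s) outside the raster")
  .rsf_loglik_cells(gamma, X, prep$cellX, prep$cell_area)
}

#' Priors for the hierarchical resource-selection model
#'
#' Individual coefficients `gamma_l ~ N(mu_gamma, Sigma_gamma)` with
#' `mu_gamma ~ N(mu_0, Sigma_0)` and `Sigma_gamma^-1 ~ Wishart((S nu)^-1, nu)`.
#'
#' @param mu_0 prior mean of the population-level coefficients.
#' @param sigma2_0 diagonal prior variance of `mu_gamma`.
#' @param nu Wishart degrees of freedom (default `p + 1`, set at fit time
#'   when `NULL`).
#' @param S Wishart scale matrix (default identity).
#' @export
rsf_priors <- function(mu_0 = 0, sigma2_0 = 100, nu = NULL, S = NULL) {
  list(mu_0 = mu_0, sigma2_0 = sigma2_0, nu = nu, S = S)
}

.ldmvnorm <- function(x, mean, prec_chol) {
  ## log N(x; mean, Sigma) with prec_chol = chol(Sigma^-1)
  z <- prec_chol %*% (x - mean)
  sum(log(diag(prec_chol))) - 0.5 * length(x) * log(2 * pi) -
    0.5 * sum(z^2)
}

#' Fit a (hierarchical) resource-selection function by MCMC
#'
#' Individual-level selection coefficients are updated by random-walk
#' Metropolis against the point-process likelihood; with two or more
#' individuals the population mean gets a conjugate normal update and the
#' population precision a conjugate Wishart update. With a single
#' individual the `N(mu_0, Sigma_0)` prior applies to `gamma` directly.
#'
#' @param locations an n x 2 matrix (one individual) or a list of such
#'   matrices (one per individual).
#' @param raster a [cov_raster()].
#' @param availability one availability region shared by all individuals,
#'   or a list (one per individual); default raster extent.
#' @param priors an [rsf_priors()] list.
#' @param mcmc an [mcmc_control()] list.
#' @return object of class `rsf_fit` with draw matrices `gamma` (per
#'   individual), `mu_gamma`, `Sigma_gamma`.
#' @export
fit_hier_rsf <- function(locations, raster, availability = NULL,
                         priors = rsf_priors(), mcmc = mcmc_control(3000L)) {
  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)
  if (is.matrix(locations) || is.data.frame(locations)) {
    locations <- list(matrix(as.numeric(as.matrix(locations)), ncol = 2))
  }
  L <- length(locations)
  shared_avail <- !is.list(availability) || inherits(availability, "availability")
  avl <- function(l) if (shared_avail) availability else availability[[l]]
  preps <- lapply(seq_len(L), function(l) .rsf_prep(raster, avl(l)))
  p <- ncol(preps[[1]]$cellX)
  Xloc <- lapply(seq_len(L), function(l) {
    pts <- matrix(as.numeric(as.matrix(locations[[l]])), ncol = 2)
    if (!all(.in_availability(avl(l), pts))) {
      stop("location(s) outside availability for individual ", l)
    }
    X <- .raster_design(raster, pts, preps[[l]]$standardize)
    if (anyNA(X)) stop("location(s) outside the raster for individual ", l)
    X
  })
  mu_0 <- rep(priors$mu_0, length.out = p)
  S0_inv <- diag(1 / rep(priors$sigma2_0, length.out = p), p)
  nu <- if (is.null(priors$nu)) p + 1 else priors$nu
  S <- if (is.null(priors$S)) diag(p) else priors$S

  gam <- matrix(0, L, p)
  mu_g <- rep(0, p)
  Sg_inv <- diag(p)
  ll <- vapply(seq_len(L), function(l) {
    .rsf_loglik_cells(gam[l, ], Xloc[[l]], preps[[l]]$cellX,
                      preps[[l]]$cell_area)
  }, numeric(1))

  n_iter <- mcmc$n_iter; burn <- mcmc$burn_in; thin <- mcmc$thin
  nkeep <- length(seq(burn + 1L, n_iter, by = thin))
  g_draws <- array(NA_real_, c(nkeep, L, p))
  mu_draws <- matrix(NA_real_, nkeep, p)
  Sg_draws <- array(NA_real_, c(nkeep, p, p))
  scale_g <- matrix(0.2, L, p)
  accg <- totg <- matrix(0, L, p)
  k_out <- 0L

  for (it in seq_len(n_iter)) {
    prec_chol <- chol(Sg_inv)
    for (l in seq_len(L)) {
      gp <- gam[l, ] + rnorm(p, 0, scale_g[l, ])
      llp <- .rsf_loglik_cells(gp, Xloc[[l]], preps[[l]]$cellX,
                               preps[[l]]$cell_area)
      pr_mean <- if (L > 1L) mu_g else mu_0
      pr_chol <- if (L > 1L) prec_chol else chol(S0_inv)
      lr <- llp + .ldmvnorm(gp, pr_mean, pr_chol) -
        ll[l] - .ldmvnorm(gam[l, ], pr_mean, pr_chol)
      if (is.finite(lr) && log(runif(1)) < lr) {
        gam[l, ] <- gp; ll[l] <- llp
        accg[l, ] <- accg[l, ] + 1
      }
      totg[l, ] <- totg[l, ] + 1
    }
    if (L > 1L) {
      ## conjugate population mean
      Prec <- L * Sg_inv + S0_inv
      ch <- chol(Prec)
      mvec <- backsolve(ch, forwardsolve(t(ch),
               Sg_inv %*% colSums(gam) + S0_inv %*% mu_0))
      mu_g <- drop(mvec + backsolve(ch, rnorm(p)))
      ## conjugate Wishart for the population precision
      Sc <- S * nu
      for (l in seq_len(L)) Sc <- Sc + tcrossprod(gam[l, ] - mu_g)
      Sg_inv <- matrix(rWishart(1, nu + L, solve(Sc)), p, p)
    }
    if (it <= burn && it %% mcmc$adapt_interval == 0L) {
      rate <- accg / pmax(totg, 1)
      scale_g <- pmin(pmax(scale_g * exp(pmin(pmax(rate - 0.3, -0.3), 0.3)),
                           1e-3), 5)
      accg[] <- 0; totg[] <- 0
    }
    if (it == burn) { accg[] <- 0; totg[] <- 0 }
    if (it > burn && (it - burn - 1L) %% thin == 0L) {
      k_out <- k_out + 1L
      g_draws[k_out, , ] <- gam
      mu_draws[k_out, ] <- if (L > 1L) mu_g else gam[1, ]
      Sg_draws[k_out, , ] <- if (L > 1L) solve(Sg_inv) else diag(p)
    }
  }
  structure(list(gamma = g_draws, mu_gamma = mu_draws,
                 Sigma_gamma = Sg_draws, n_individuals = L,
                 layers = names(raster$layers),
                 acceptance = mean(accg / pmax(totg, 1)),
                 standardize = preps[[1]]$standardize, mcmc = mcmc),
            class = "rsf_fit")
}

#' @export
print.rsf_fit <- function(x, ...) {
  cat(sprintf("Hierarchical RSF fit: %d individual(s), %d kept draws\n",
              x$n_individuals, nrow(x$mu_gamma)))
  med <- apply(x$mu_gamma, 2, median)
  qs <- apply(x$mu_gamma, 2, quantile, c(0.025, 0.975))
  for (j in seq_along(med)) {
    cat(sprintf("  %s: %.3f (95%% CI %.3f, %.3f)\n",
                x$layers[j], med[j], qs[1, j], qs[2, j]))
  }
  invisible(x)
}

#' Joint location and resource-selection model
#'
#' Couples the azimuthal telemetry model with the resource-selection point
#' process: inside the availability region the location prior is
#' proportional to `exp(x(mu)' gamma)` (instead of uniform), so the
#' selection surface feeds back into the location estimation, and the
#' location draws in turn drive the `gamma` update each sweep. With
#' `gamma` fixed at zero the model reduces exactly to [fit_atm()]
#' restricted to the availability region.
#'
#' @param obs azimuth table for a single individual (see [fit_atm()]).
#' @param raster a [cov_raster()] of selection covariates.
#' @param radius_r support radius (m).
#' @param availability availability region (default raster extent).
#' @param kappa_model concentration model (see [kappa_fixed()]).
#' @param gamma `NULL` to estimate the selection coefficients, or a fixed
#'   numeric vector (e.g. zeros for the reduction check).
#' @param priors an [rsf_priors()] list; `mu_0`/`sigma2_0` act as the
#'   (independent normal) prior for `gamma`.
#' @param mcmc an [mcmc_control()] list.
#' @return an `atm_fit` whose `draws$gamma` holds the selection
#'   coefficient draws (when estimated).
#' @export
fit_atm_rsf <- function(obs, raster, radius_r, availability = NULL,
                        kappa_model = kappa_homogeneous(), gamma = NULL,
                        priors = rsf_priors(), mcmc = mcmc_control()) {
  prep <- .atm_prepare(obs)
  if (is.null(availability)) availability <- availability_extent(raster)
  rp <- .rsf_prep(raster, availability)
  p <- ncol(rp$cellX)
  update_gamma <- is.null(gamma)
  if (!update_gamma && length(gamma) != p) stop("gamma has wrong length")
  rsf <- list(raster = raster, availability = availability,
              standardize = rp$standardize, cellX = rp$cellX,
              cell_area = rp$cell_area,
              gamma = if (update_gamma) rep(0, p) else as.numeric(gamma),
              update_gamma = update_gamma,
              prior_mean = rep(priors$mu_0, length.out = p),
              prior_var = rep(priors$sigma2_0, length.out = p))
  .atm_engine(prep, radius_r, kappa_model, mcmc, rsf = rsf)
}

#' Benchmark resource-selection inference under location uncertainty
#'
#' For each combination of sample size and covariate autocorrelation,
#' simulates a GRF covariate raster, draws true locations from the point
#' process, simulates azimuths (random design), and fits three models:
#' the RSF on the true locations, the RSF on classical triangulation
#' point estimates (uncertainty ignored), and the joint ATM-RSF. Records
#' posterior medians and 50%/95% intervals of both selection coefficients.
#'
#' @param n_locations vector of location sample sizes.
#' @param autocorrelation vector of autocorrelation levels.
#' @param n_reps replicates per cell.
#' @param nx,ny,cellsize raster dimensions.
#' @param gamma_true true selection coefficients (continuous, categorical).
#' @param kappa_true bearing concentration.
#' @param n_theta azimuths per location.
#' @param radius_r ATM support radius (m).
#' @param mcmc_atm,mcmc_rsf MCMC controls for the joint and location-free
#'   fits.
#' @param distance_sampler observer distance distribution.
#' @param seed optional seed.
#' @return data.frame, one row per cell x replicate x model.
#' @export
rsf_benchmark <- function(n_locations = c(50L, 200L),
                          autocorrelation = c("low", "moderate", "high"),
                          n_reps = 10L, nx = 40L, ny = 40L, cellsize = 50,
                          gamma_true = c(1, 1), kappa_true = 50,
                          n_theta = 3L, radius_r = 1000,
                          mcmc_atm = mcmc_control(2000L),
                          mcmc_rsf = mcmc_control(2000L),
                          distance_sampler = function(n) runif(n, 100, 1000),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  qsum <- function(dr, model, N, ac, rep_i) {
    data.frame(model = model, n_locations = N, autocorrelation = ac,
               rep = rep_i,
               gamma1 = median(dr[, 1]), gamma2 = median(dr[, 2]),
               g1_lo50 = quantile(dr[, 1], 0.25), g1_hi50 = quantile(dr[, 1], 0.75),
               g1_lo95 = quantile(dr[, 1], 0.025), g1_hi95 = quantile(dr[, 1], 0.975),
               g2_lo50 = quantile(dr[, 2], 0.25), g2_hi50 = quantile(dr[, 2], 0.75),
               g2_lo95 = quantile(dr[, 2], 0.025), g2_hi95 = quantile(dr[, 2], 0.975),
               row.names = NULL)
  }
  for (ac in autocorrelation) {
    for (N in n_locations) {
      for (r in seq_len(n_reps)) {
        raster <- simulate_grf_covariates(nx, ny, cellsize, ac)
        avail <- availability_extent(raster)
        truths <- sample_ipp_locations(gamma_true, raster, N, avail)
        obs <- vector("list", N)
        lenth <- matrix(NA_real_, N, 2)
        for (i in seq_len(N)) {
          st <- generate_design(truths[i, ], "random", n_theta,
                                distance_sampler)
          o <- simulate_relocation(truths[i, ], st, kappa_true)
          o$relocation <- i
          obs[[i]] <- o
          f <- triangulate(st, o$theta, method = "mle-fixed-point")
          if (isTRUE(f$converged)) lenth[i, ] <- f$estimate
        }
        obs <- do.call(rbind, obs)

        f_true <- fit_hier_rsf(truths, raster, avail, mcmc = mcmc_rsf)
        rows[[length(rows) + 1L]] <- qsum(f_true$mu_gamma, "true", N, ac, r)

        ok <- !is.na(lenth[, 1]) & .in_availability(avail, lenth)
        f_len <- fit_hier_rsf(lenth[ok, , drop = FALSE], raster, avail,
                              mcmc = mcmc_rsf)
        rows[[length(rows) + 1L]] <- qsum(f_len$mu_gamma, "lenth", N, ac, r)

        f_atm <- fit_atm_rsf(obs, raster, radius_r, avail,
                             kappa_model = kappa_homogeneous(),
                             mcmc = mcmc_atm)
        rows[[length(rows) + 1L]] <- qsum(f_atm$draws$gamma, "atm", N, ac, r)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
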