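#' Concentration models for the azimuthal telemetry model
#'
#' The bearing-error concentration kappa can be handled three ways:
#'
#' * `kappa_fixed(kappa)`: known, fixed concentration (mostly for
#'   validation against exact oracles).
#' * `kappa_homogeneous()`: a single shared concentration for every
#'   azimuth, sampled with a diffuse normal prior on `log(kappa)`. This is
#'   the configuration used in the study-design benchmark.
#' * `kappa_hier(formula)`: the full hierarchy
#'   `log(kappa_ij) ~ N(w_ij' beta + alpha1 * log(d_ij), sigma2_kappa)`
#'   where `w_ij` is a design row built from covariate columns of the
#'   azimuth table (e.g. observer effects), `d_ij` is the station-animal
#'   distance (optional effect), with conjugate priors
#'   `beta ~ N(mu_beta, Sigma_beta)` and
#'   `sigma2_kappa ~ IG(alpha_sigma, beta_sigma)` and a normal prior on
#'   `alpha1`.
#'
#' @param kappa fixed concentration (>= 0).
#' @return a `kappa_model` specification list.
#' @export
kappa_fixed <- function(kappa) {
  if (!is.finite(kappa) || kappa < 0) stop("kappa must be >= 0")
  structure(list(type = "fixed", kappa = kappa), class = "kappa_model")
}

#' @rdname kappa_fixed
#' @param mean,sd prior mean and sd of the shared `log(kappa)`.
#' @export
kappa_homogeneous <- function(mean = 0, sd = 10) {
  structure(list(type = "homogeneous", prior_mean = mean, prior_sd = sd),
            class = "kappa_model")
}

#' @rdname kappa_fixed
#' @param formula design formula for `log(kappa)` built from azimuth-table
#'   columns; `~ 1` is the intercept-only hierarchy.
#' @param distance_effect include the `alpha1 * log(d)` station-animal
#'   distance term.
#' @param mu_beta,sigma2_beta prior mean and (diagonal) prior variance of
#'   the coefficients.
#' @param alpha_sigma,beta_sigma inverse-gamma hyperparameters for
#'   `sigma2_kappa`.
#' @param alpha1_var prior variance of the distance coefficient.
#' @export
kappa_hier <- function(formula = ~1, distance_effect = FALSE,
                       mu_beta = 0, sigma2_beta = 4,
                       alpha_sigma = 2, beta_sigma = 1, alpha1_var = 4) {
  structure(list(type = "hier", formula = formula,
                 distance_effect = distance_effect,
                 mu_beta = mu_beta, sigma2_beta = sigma2_beta,
                 alpha_sigma = alpha_sigma, beta_sigma = beta_sigma,
                 alpha1_var = alpha1_var),
            class = "kappa_model")
}

#' MCMC control settings
#'
#' @param n_iter total iterations.
#' @param burn_in burn-in iterations (default 20% of `n_iter`); proposal
#'   scales are adapted toward acceptance rates of roughly 0.2-0.45 during
#'   burn-in and frozen afterwards.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed optional integer seed; identical seed and configuration give
#'   identical draws.
#' @param adapt_interval iterations between proposal-scale adaptations.
#' @param store_kappa store per-azimuth log-kappa draws (hierarchical model).
#' @export
mcmc_control <- function(n_iter = 5000L, burn_in = NULL, thin = 1L,
                         seed = NULL, adapt_interval = 50L,
                         store_kappa = TRUE) {
  n_iter <- as.integer(n_iter)
  if (is.null(burn_in)) burn_in <- as.integer(ceiling(0.2 * n_iter))
  stopifnot(n_iter > burn_in, thin >= 1L)
  list(n_iter = n_iter, burn_in = as.integer(burn_in),
       thin = as.integer(thin), seed = seed,
       adapt_interval = as.integer(adapt_interval),
       store_kappa = isTRUE(store_kappa))
}

## Normalize an azimuth table into the padded-matrix layout the samplers use.
## obs needs columns x, y (station, m), one of theta (math radians) or
## azimuth (compass degrees), and a relocation id (+ optional individual).
.atm_prepare <- function(obs) {
  obs <- as.data.frame(obs)
  if (!all(c("x", "y") %in% names(obs))) stop("missing station columns x, y")
  if (!"theta" %in% names(obs)) {
    if (!"azimuth" %in% names(obs)) stop("need a theta or azimuth column")
    obs$theta <- compass_to_math(obs$azimuth)
  }
  if (!"relocation" %in% names(obs)) stop("missing relocation id column")
  if (!all(is.finite(obs$x)) || !all(is.finite(obs$y))) {
    stop("non-finite station coordinates")
  }
  id <- if ("individual" %in% names(obs)) {
    paste(obs$individual, obs$relocation, sep = "\r")
  } else {
    as.character(obs$relocation)
  }
  rel <- factor(id, levels = unique(id))
  M <- nlevels(rel)
  ri <- as.integer(rel)
  J <- tabulate(ri, M)
  Jmax <- max(J)
  ## position of each obs within its relocation
  pos <- ave(seq_along(ri), ri, FUN = seq_along)
  lin <- (pos - 1L) * M + ri  # column-major linear index into M x Jmax
  pad <- function(v, fill_from_first = TRUE) {
    m <- matrix(NA_real_, M, Jmax)
    m[lin] <- v
    if (fill_from_first) {
      ## pad unused cells with the relocation's first value so matrix ops
      ## stay NA-free; padded cells carry zero likelihood weight
      for (j in seq_len(Jmax)) {
        miss <- is.na(m[, j])
        if (any(miss)) m[miss, j] <- m[miss, 1]
      }
    }
    m
  }
  mask <- matrix(FALSE, M, Jmax); mask[lin] <- TRUE
  list(obs = obs, M = M, n_obs = nrow(obs), rel = rel, ri = ri, J = J,
       Jmax = Jmax, lin = lin, mask = mask, wmask = mask * 1,
       ZX = pad(obs$x), ZY = pad(obs$y), TH = pad(obs$theta),
       ids = unique(data.frame(
         individual = if ("individual" %in% names(obs)) obs$individual else NA,
         relocation = obs$relocation,
         stringsAsFactors = FALSE)))
}

.rowmin <- function(m) {
  out <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) out <- pmin(out, m[, j])
  out
}

#' Fit the azimuthal telemetry model by MCMC
#'
#' Hierarchical Bayesian estimation of animal locations from compass
#' bearings. Each bearing follows a von Mises distribution around the true
#' station-to-animal direction; each location has a uniform prior over the
#' union of circles of radius `radius_r` around its stations; the
#' concentration is fixed, shared, or modelled hierarchically (see
#' [kappa_fixed()]). Sampling is Metropolis-within-Gibbs: random-walk
#' proposals for each location (rejected outside its support), random-walk
#' updates of log-concentrations, and conjugate updates for the
#' concentration regression coefficients and variance.
#'
#' @param obs azimuth table: data.frame with station coordinates `x`, `y`
#'   (m), bearings as `azimuth` (compass degrees) or `theta` (math
#'   radians), a `relocation` id, optionally an `individual` id and
#'   covariate columns used by [kappa_hier()] formulas.
#' @param radius_r support radius in meters; `NULL` uses
#'   [default_radius()] of all stations.
#' @param kappa_model a [kappa_fixed()], [kappa_homogeneous()] or
#'   [kappa_hier()] specification.
#' @param mcmc an [mcmc_control()] list.
#' @return an object of class `atm_fit`; see Details.
#' @details The returned fit contains `mu_draws` (array: kept iterations x
#'   relocations x 2), the per-relocation `support` regions, concentration
#'   draws (`log_kappa_shared`, or `beta`/`sigma2_kappa`/`alpha1`/
#'   `log_kappa`), acceptance rates, and the control settings. Use
#'   [location_draws()] to extract one relocation's posterior and
#'   [hpd_region()] for isopleths.
#' @export
fit_atm <- function(obs, radius_r = NULL,
                    kappa_model = kappa_homogeneous(),
                    mcmc = mcmc_control()) {
  prep <- .atm_prepare(obs)
  if (prep$n_obs == 0L) stop("empty azimuth table")
  if (is.null(radius_r)) radius_r <- default_radius(cbind(prep$obs$x, prep$obs$y))
  .atm_engine(prep, radius_r, kappa_model, mcmc, rsf = NULL)
}

## The Metropolis-within-Gibbs engine shared by fit_atm and fit_atm_rsf.
## When `rsf` is non-NULL the location prior (within the support) is
## proportional to exp(x(mu)' gamma) restricted to the availability region,
## and gamma is optionally updated each sweep.
.atm_engine <- function(prep, radius_r, kappa_model, mcmc, rsf = NULL) {
  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)
  M <- prep$M; Jmax <- prep$Jmax
  ZX <- prep$ZX; ZY <- prep$ZY; TH <- prep$TH
  wm <- prep$wmask; lin <- prep$lin
  n_obs <- prep$n_obs

  supports <- lapply(seq_len(M), function(i) {
    keep <- prep$mask[i, ]
    support_region(cbind(ZX[i, keep], ZY[i, keep]), radius_r)
  })
  r2 <- radius_r^2

  ## --- initial locations: intersection average clipped into the support
  mu <- matrix(NA_real_, M, 2)
  for (i in seq_len(M)) {
    keep <- prep$mask[i, ]
    st <- cbind(ZX[i, keep], ZY[i, keep])
    b <- TH[i, keep]
    p <- NULL
    if (nrow(st) >= 2L) {
      p <- intersection_average(st, b, fallback_to_lines = TRUE)
    }
    if (is.null(p)) {
      p <- st[1, ] + 0.5 * radius_r * c(cos(b[1]), sin(b[1]))
    }
    if (!in_support(supports[[i]], p)) {
      ## pull toward the nearest station until inside
      dists <- sqrt((st[, 1] - p[1])^2 + (st[, 2] - p[2])^2)
      jn <- which.min(dists)
      p <- st[jn, ] + (p - st[jn, ]) * (0.95 * radius_r / dists[jn])
    }
    mu[i, ] <- p
  }

  ## --- rsf state (before the geometry caches: clamping may move mu)
  use_rsf <- !is.null(rsf)
  if (use_rsf) {
    gamma <- rsf$gamma
    ## clamp starting locations into the raster so covariates are defined;
    ## the chain then moves into the availability-support intersection
    ext <- raster_extent(rsf$raster)
    eps <- rsf$raster$cellsize * 1e-3
    mu[, 1] <- pmin(pmax(mu[, 1], ext["xmin"] + eps), ext["xmax"] - eps)
    mu[, 2] <- pmin(pmax(mu[, 2], ext["ymin"] + eps), ext["ymax"] - eps)
    xmu <- .raster_design(rsf$raster, mu, rsf$standardize)
    if (anyNA(xmu)) stop(paste(
      "initial location outside raster for relocation(s):",
      paste(which(is.na(xmu[, 1])), collapse = ", ")))
    rsf_prior_mu <- drop(xmu %*% gamma)
  } else {
    rsf_prior_mu <- numeric(M)
  }

  ## --- kappa state
  type <- kappa_model$type
  dxc <- mu[, 1] - ZX; dyc <- mu[, 2] - ZY
  d2c <- dxc^2 + dyc^2
  ttc <- atan2(dyc, dxc)
  res0 <- (TH - ttc)[lin]
  Rbar <- sqrt(mean(cos(res0))^2 + mean(sin(res0))^2)
  kap0 <- min(max(.a1inv(Rbar), 0.5), 1e4)

  hier <- type == "hier"
  use_dist <- hier && isTRUE(kappa_model$distance_effect)
  if (hier) {
    W <- model.matrix(kappa_model$formula, prep$obs)
    p <- ncol(W)
    if (qr(W)$rank < p) stop("rank-deficient kappa design matrix")
    mu_beta <- rep(kappa_model$mu_beta, length.out = p)
    Sb_inv <- diag(1 / rep(kappa_model$sigma2_beta, length.out = p), p)
    xi <- rep(log(kap0), n_obs)
    beta <- qr.solve(W, xi)
    sigma2 <- 0.5
    alpha1 <- 0
    WB <- drop(W %*% beta)
  }
  if (type == "homogeneous") xi_s <- log(kap0)
  KAP <- matrix(switch(type, fixed = kappa_model$kappa,
                       homogeneous = exp(xi_s), hier = 0), M, Jmax)
  if (hier) KAP[lin] <- exp(xi)

  ## current per-relocation log-likelihood for the mu update (I0 terms drop
  ## because kappa is held fixed within the location update)
  loglik_mu <- function(ttm, d2m, kapm, meanmat = NULL, sdv = NULL) {
    contrib <- kapm * cos(TH - ttm) * wm
    ll <- rowSums(contrib)
    if (use_dist) {
      pm <- dnorm(xi_mat, meanmat, sdv, log = TRUE) * wm
      ll <- ll + rowSums(pm)
    }
    ll
  }
  xi_mat <- NULL
  mean_mat <- NULL
  if (use_dist) {
    xi_mat <- matrix(0, M, Jmax); xi_mat[lin] <- xi
    wb_mat <- matrix(0, M, Jmax); wb_mat[lin] <- WB
  }

  curr_mean <- function(d2m) {
    if (use_dist) wb_mat + alpha1 * 0.5 * log(d2m) else NULL
  }
  mean_mat <- curr_mean(d2c)
  ll_cur <- loglik_mu(ttc, d2c, KAP, mean_mat, if (use_dist) sqrt(sigma2))

  ## --- proposal scales and adaptation
  scale_mu <- rep(radius_r / 20, M)
  scale_xi <- if (hier) rep(0.8, n_obs) else 0.5
  scale_a1 <- 0.2
  scale_g <- if (use_rsf && rsf$update_gamma) rep(0.15, length(rsf$gamma)) else NULL
  acc_mu <- numeric(M); acc_xi <- if (hier) numeric(n_obs) else 0
  acc_a1 <- 0; acc_g <- 0
  tot_mu <- numeric(M); tot_xi <- if (hier) numeric(n_obs) else 0
  tot_a1 <- 0; tot_g <- 0

  n_iter <- mcmc$n_iter; burn <- mcmc$burn_in; thin <- mcmc$thin
  keep_iter <- seq(burn + 1L, n_iter, by = thin)
  nkeep <- length(keep_iter)
  mu_draws <- array(NA_real_, c(nkeep, M, 2))
  if (type == "homogeneous") lk_draws <- numeric(nkeep)
  if (hier) {
    beta_draws <- matrix(NA_real_, nkeep, p,
                         dimnames = list(NULL, colnames(W)))
    s2_draws <- numeric(nkeep)
    a1_draws <- if (use_dist) numeric(nkeep) else NULL
    xi_draws <- if (mcmc$store_kappa) matrix(NA_real_, nkeep, n_obs) else NULL
  }
  if (use_rsf) gamma_draws <- matrix(NA_real_, nkeep, length(rsf$gamma))

  k_out <- 0L
  logI0 <- log_bessel_i0

  for (it in seq_len(n_iter)) {
    adapting <- it <= burn

    ## ---- location update (vectorised over relocations)
    prop <- mu + cbind(rnorm(M, 0, scale_mu), rnorm(M, 0, scale_mu))
    dxp <- prop[, 1] - ZX; dyp <- prop[, 2] - ZY
    d2p <- dxp^2 + dyp^2
    inside <- .rowmin(d2p) <= r2
    if (use_rsf) {
      xp <- .raster_design(rsf$raster, prop, rsf$standardize)
      avail_ok <- !is.na(xp[, 1]) &
        .in_availability(rsf$availability, prop)
      inside <- inside & avail_ok
      rsf_prop <- ifelse(inside, drop(xp %*% gamma), -Inf)
    }
    ttp <- atan2(dyp, dxp)
    mm_p <- curr_mean(d2p)
    ll_prop <- loglik_mu(ttp, d2p, KAP, mm_p, if (use_dist) sqrt(sigma2))
    logr <- ll_prop - ll_cur
    if (use_rsf) logr <- logr + rsf_prop - rsf_prior_mu
    acc <- inside & is.finite(logr) & (log(runif(M)) < logr)
    if (any(acc)) {
      mu[acc, ] <- prop[acc, ]
      ttc[acc, ] <- ttp[acc, , drop = FALSE]
      d2c[acc, ] <- d2p[acc, , drop = FALSE]
      ll_cur[acc] <- ll_prop[acc]
      if (use_dist) mean_mat[acc, ] <- mm_p[acc, , drop = FALSE]
      if (use_rsf) {
        xmu[acc, ] <- xp[acc, , drop = FALSE]
        rsf_prior_mu[acc] <- rsf_prop[acc]
      }
    }
    acc_mu <- acc_mu + acc; tot_mu <- tot_mu + 1

    ## ---- concentration update
    cosres <- cos(TH - ttc)
    if (type == "homogeneous") {
      Scos <- sum(cosres[lin])
      xi_p <- xi_s + rnorm(1, 0, scale_xi)
      lt <- function(x) {
        if (abs(x) > 30) return(-Inf)
        k <- exp(x)
        k * Scos - n_obs * logI0(k) +
          dnorm(x, kappa_model$prior_mean, kappa_model$prior_sd, log = TRUE)
      }
      if (log(runif(1)) < lt(xi_p) - lt(xi_s)) {
        xi_s <- xi_p
        KAP[] <- exp(xi_s)
        mean_mat <- curr_mean(d2c)
        ll_cur <- loglik_mu(ttc, d2c, KAP, mean_mat, if (use_dist) sqrt(sigma2))
        acc_xi <- acc_xi + 1
      }
      tot_xi <- tot_xi + 1
    } else if (hier) {
      cr <- cosres[lin]
      mloc <- WB + if (use_dist) alpha1 * 0.5 * log(d2c[lin]) else 0
      xi_p <- xi + rnorm(n_obs, 0, scale_xi)
      kp <- exp(pmin(xi_p, 30)); kc <- exp(xi)
      lr <- (kp - kc) * cr - (logI0(kp) - logI0(kc)) +
        dnorm(xi_p, mloc, sqrt(sigma2), log = TRUE) -
        dnorm(xi, mloc, sqrt(sigma2), log = TRUE)
      ## reject log-kappa excursions beyond numeric range
      accx <- !is.na(lr) & abs(xi_p) <= 30 & (log(runif(n_obs)) < lr)
      xi[accx] <- xi_p[accx]
      KAP[lin] <- exp(xi)
      acc_xi <- acc_xi + accx; tot_xi <- tot_xi + 1
      if (use_dist) { xi_mat[lin] <- xi }

      ## conjugate beta
      yresp <- xi - if (use_dist) alpha1 * 0.5 * log(d2c[lin]) else 0
      Prec <- crossprod(W) / sigma2 + Sb_inv
      ch <- chol(Prec)
      bmean <- backsolve(ch, forwardsolve(t(ch),
                crossprod(W, yresp) / sigma2 + Sb_inv %*% mu_beta))
      beta <- drop(bmean + backsolve(ch, rnorm(p)))
      WB <- drop(W %*% beta)
      if (use_dist) wb_mat[lin] <- WB

      ## conjugate sigma2 (inverse gamma)
      rss <- sum((yresp - WB)^2)
      sigma2 <- 1 / rgamma(1, kappa_model$alpha_sigma + n_obs / 2,
                           kappa_model$beta_sigma + rss / 2)

      ## alpha1 random walk
      if (use_dist) {
        ld <- 0.5 * log(d2c[lin])
        lt_a <- function(a) {
          sum(dnorm(xi, WB + a * ld, sqrt(sigma2), log = TRUE)) +
            dnorm(a, 0, sqrt(kappa_model$alpha1_var), log = TRUE)
        }
        a_p <- alpha1 + rnorm(1, 0, scale_a1)
        if (log(runif(1)) < lt_a(a_p) - lt_a(alpha1)) {
          alpha1 <- a_p; acc_a1 <- acc_a1 + 1
        }
        tot_a1 <- tot_a1 + 1
        mean_mat <- curr_mean(d2c)
      }
      ## refresh cached mu-loglik (kappa / prior parameters moved)
      ll_cur <- loglik_mu(ttc, d2c, KAP, mean_mat, if (use_dist) sqrt(sigma2))
    }

    ## ---- RSF coefficient update
    if (use_rsf && rsf$update_gamma) {
      gp <- gamma + rnorm(length(gamma), 0, scale_g)
      lr <- .rsf_loglik_cells(gp, xmu, rsf$cellX, rsf$cell_area) +
        sum(dnorm(gp, rsf$prior_mean, sqrt(rsf$prior_var), log = TRUE)) -
        .rsf_loglik_cells(gamma, xmu, rsf$cellX, rsf$cell_area) -
        sum(dnorm(gamma, rsf$prior_mean, sqrt(rsf$prior_var), log = TRUE))
      if (is.finite(lr) && log(runif(1)) < lr) {
        gamma <- gp
        rsf_prior_mu <- drop(xmu %*% gamma)
        acc_g <- acc_g + 1
      }
      tot_g <- tot_g + 1
    }

    ## ---- adaptation during burn-in
    if (adapting && it %% mcmc$adapt_interval == 0L) {
      ## scales are bounded to keep the adaptation from ratcheting into the
      ## degenerate high-concentration spike (see vignette, identifiability)
      rate <- acc_mu / tot_mu
      scale_mu <- pmin(pmax(scale_mu * exp(pmin(pmax(rate - 0.3, -0.3), 0.3)),
                            radius_r / 2000), radius_r)
      acc_mu[] <- 0; tot_mu[] <- 0
      if (type == "homogeneous") {
        rx <- acc_xi / tot_xi
        scale_xi <- min(max(scale_xi * exp(min(max(rx - 0.3, -0.3), 0.3)),
                            0.02), 5)
        acc_xi <- 0; tot_xi <- 0
      } else if (hier) {
        rx <- acc_xi / tot_xi
        scale_xi <- pmin(pmax(scale_xi * exp(pmin(pmax(rx - 0.3, -0.3), 0.3)),
                              0.05), 5)
        acc_xi[] <- 0; tot_xi <- 0
        if (use_dist && tot_a1 > 0) {
          scale_a1 <- scale_a1 * exp(min(max(acc_a1 / tot_a1 - 0.3, -0.3), 0.3))
          acc_a1 <- 0; tot_a1 <- 0
        }
      }
      if (use_rsf && rsf$update_gamma && tot_g > 0) {
        scale_g <- scale_g * exp(min(max(acc_g / tot_g - 0.3, -0.3), 0.3))
        acc_g <- 0; tot_g <- 0
      }
    }
    if (it == burn) {
      ## acceptance rates reported over the post-burn-in phase only
      acc_mu[] <- 0; tot_mu[] <- 0
      if (hier) { acc_xi[] <- 0; tot_xi <- 0 } else { acc_xi <- 0; tot_xi <- 0 }
      acc_a1 <- 0; tot_a1 <- 0; acc_g <- 0; tot_g <- 0
    }

    ## ---- storage
    if (it > burn && (it - burn - 1L) %% thin == 0L) {
      k_out <- k_out + 1L
      mu_draws[k_out, , ] <- mu
      if (type == "homogeneous") lk_draws[k_out] <- xi_s
      if (hier) {
        beta_draws[k_out, ] <- beta
        s2_draws[k_out] <- sigma2
        if (use_dist) a1_draws[k_out] <- alpha1
        if (!is.null(xi_draws)) xi_draws[k_out, ] <- xi
      }
      if (use_rsf) gamma_draws[k_out, ] <- gamma
    }
  }

  draws <- list()
  if (type == "homogeneous") draws$log_kappa_shared <- lk_draws
  if (hier) {
    draws$beta <- beta_draws
    draws$sigma2_kappa <- s2_draws
    if (use_dist) draws$alpha1 <- a1_draws
    if (!is.null(xi_draws)) draws$log_kappa <- xi_draws
  }
  if (use_rsf) draws$gamma <- gamma_draws

  out <- structure(list(
    mu_draws = mu_draws,
    relocations = prep$ids,
    support = supports,
    radius_r = radius_r,
    kappa_model = kappa_model,
    draws = draws,
    acceptance = list(
      mu = unname(ifelse(tot_mu > 0, acc_mu / pmax(tot_mu, 1), NA)),
      kappa = if (hier) mean(acc_xi / pmax(tot_xi, 1)) else
        if (type == "homogeneous") acc_xi / max(tot_xi, 1) else NA,
      gamma = if (use_rsf && rsf$update_gamma) acc_g / max(tot_g, 1) else NA),
    mcmc = mcmc,
    n_obs = n_obs,
    rsf = if (use_rsf) rsf["standardize"] else NULL),
    class = "atm_fit")
  out
}

#' Extract one relocation's posterior location draws
#'
#' @param fit an `atm_fit`.
#' @param i relocation index (row of `fit$relocations`).
#' @return matrix of draws with columns `x`, `y`.
#' @export
location_draws <- function(fit, i = 1L) {
  m <- fit$mu_draws[, i, , drop = FALSE]
  out <- matrix(m, dim(m)[1], 2)
  colnames(out) <- c("x", "y")
  out
}

#' Effective sample size of a (possibly autocorrelated) draw sequence
#'
#' `n / (1 + 2 sum rho_k)` with the autocorrelation sum truncated at the
#' first non-positive estimate.
#'
#' @param x numeric vector of MCMC draws.
#' @return effective sample size.
#' @export
effective_size <- function(x) {
  n <- length(x)
  if (n < 10L || sd(x) == 0) return(ifelse(sd(x) == 0, 1, n))
  lag_max <- min(n - 1L, 200L)
  rho <- drop(acf(x, lag.max = lag_max, plot = FALSE)$acf)[-1]
  neg <- which(rho <= 0)
  if (length(neg)) rho <- rho[seq_len(neg[1] - 1L)]
  max(1, n / (1 + 2 * sum(rho)))
}

#' @export
print.atm_fit <- function(x, ...) {
  cat("Azimuthal telemetry model fit\n")
  cat(sprintf("  %d relocations, %d azimuths; support radius %.0f m\n",
              dim(x$mu_draws)[2], x$n_obs, x$radius_r))
  cat(sprintf("  kappa model: %s\n", x$kappa_model$type))
  cat(sprintf("  %d kept draws; mean location acceptance %.2f\n",
              dim(x$mu_draws)[1], mean(x$acceptance$mu)))
  if (!is.null(x$draws$log_kappa_shared)) {
    cat(sprintf("  posterior median kappa: %.1f\n",
                exp(median(x$draws$log_kappa_shared))))
  }
  if (!is.null(x$draws$beta)) {
    cat("  posterior median beta:",
        paste(sprintf("%.2f", apply(x$draws$beta, 2, median)), collapse = ", "),
        sprintf("; sigma2_kappa: %.2f\n", median(x$draws$sigma2_kappa)))
  }
  invisible(x)
}
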