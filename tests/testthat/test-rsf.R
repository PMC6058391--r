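test_that("GRF covariates have balanced classes and unit marginal moments", {
  set.seed(50)
  r <- simulate_grf_covariates(30, 30, 25, "moderate")
  expect_equal(mean(r$layers$cat), 0.5, tolerance = 1 / 900)
  expect_true(all(r$layers$cat %in% c(0, 1)))
  ## marginal moments pooled over replicates
  v <- replicate(20, {
    g <- simulate_grf_covariates(12, 12, 25, "moderate")$layers$cont
    g[5, 8]
  })
  expect_equal(mean(v), 0, tolerance = 0.8)   # 20 replicates, sd 1
  vals <- replicate(20, as.numeric(simulate_grf_covariates(
    20, 20, 25, "low")$layers$cont))
  expect_equal(mean(vals), 0, tolerance = 0.15)
  expect_equal(var(as.numeric(vals)), 1, tolerance = 0.15)
})

test_that("autocorrelation level orders the empirical correlogram", {
  set.seed(51)
  lag_cor <- function(ac) {
    mean(replicate(20, {
      g <- simulate_grf_covariates(30, 30, 25, ac)$layers$cont
      cor(as.numeric(g[1:25, ]), as.numeric(g[6:30, ]))  # lag 5 in x
    }))
  }
  cl <- lag_cor("low"); cm <- lag_cor("moderate"); ch <- lag_cor("high")
  expect_lt(cl, cm)
  expect_lt(cm, ch)
})

test_that("point-process sampler is uniform at gamma = 0 and follows exp(x'gamma)", {
  set.seed(52)
  r <- sim_test_raster(20, 20, 50)
  av <- availability_extent(r)
  ## uniform null: chi-square GOF over cells
  pts <- sample_ipp_locations(c(0, 0), r, 1e4, av)
  expect_true(all(.in_availability <- pts[, 1] >= 0 & pts[, 1] <= 1000 &
                    pts[, 2] >= 0 & pts[, 2] <= 1000))
  i <- floor(pts[, 1] / 50) + 1; j <- floor(pts[, 2] / 50) + 1
  counts <- table(factor(i + 20 * (j - 1), levels = 1:400))
  expect_gt(chisq.test(as.numeric(counts))$p.value, 0.01)
  ## binary covariate: intensity ratio equals exp(gamma)
  rb <- cov_raster(c(0, 0), 50, layers = list(
    cont = matrix(0, 20, 20),
    cat = matrix(rbinom(400, 1, 0.5), 20, 20)))
  g <- 0.8
  pb <- sample_ipp_locations(c(0, g), rb, 3e4, availability_extent(rb))
  v <- raster_values(rb, pb, "cat")
  n1 <- sum(rb$layers$cat); n0 <- 400 - n1
  ratio <- (sum(v == 1) / n1) / (sum(v == 0) / n0)
  expect_equal(ratio, exp(g), tolerance = 0.1)
})

test_that("RSF log-likelihood matches its closed forms and the cell-sum oracle", {
  set.seed(53)
  r <- sim_test_raster(20, 20, 50)
  av <- availability_extent(r)
  pts <- sample_ipp_locations(c(0.5, 0.5), r, 40, av)
  ## gamma = 0: minus n log(available area)
  expect_equal(rsf_log_likelihood(c(0, 0), pts, r, av),
               -40 * log(1000 * 1000), tolerance = 1e-10)
  ## adding a constant to a covariate leaves the likelihood unchanged
  r2 <- r
  r2$layers$cont <- r$layers$cont + 5  # standardisation absorbs the shift
  g <- c(0.7, -0.4)
  expect_equal(rsf_log_likelihood(g, pts, r, av),
               rsf_log_likelihood(g, pts, r2, av), tolerance = 1e-10)
  ## independent double-loop cell-sum oracle
  prep <- aztelem:::.rsf_prep(r, av)
  X <- aztelem:::.raster_design(r, pts, prep$standardize)
  den <- 0
  for (k in seq_len(nrow(prep$cellX))) {
    den <- den + exp(sum(prep$cellX[k, ] * g)) * prep$cell_area
  }
  expect_equal(rsf_log_likelihood(g, pts, r, av),
               sum(X %*% g) - 40 * log(den), tolerance = 1e-10)
  ## normalisation: cell probabilities sum to one for any gamma
  for (gg in list(c(0, 0), c(1, -2), c(-0.3, 0.9))) {
    p <- exp(prep$cellX %*% gg) * prep$cell_area
    expect_equal(sum(p / sum(p)), 1, tolerance = 1e-12)
  }
  expect_error(rsf_log_likelihood(g, matrix(c(-500, -500), 1, 2), r, av),
               "outside")
})

test_that("posterior mode of the single-individual RSF matches a numerical optimizer", {
  set.seed(54)
  r <- sim_test_raster(25, 25, 40, "moderate")
  av <- availability_extent(r)
  gtrue <- c(1, 0.6)
  pts <- sample_ipp_locations(gtrue, r, 400, av)
  fit <- fit_hier_rsf(pts, r, av, mcmc = mcmc_control(2500L, seed = 11))
  post_med <- apply(fit$mu_gamma, 2, median)
  ## independent route: direct optimisation of the concave log-likelihood
  opt <- optim(c(0, 0), function(g) -rsf_log_likelihood(g, pts, r, av),
               method = "BFGS")
  expect_equal(post_med, opt$par, tolerance = 0.1)
  expect_equal(post_med, gtrue, tolerance = 0.35)
})

test_that("flat covariates give centred-at-zero selection posteriors", {
  set.seed(55)
  r <- cov_raster(c(0, 0), 50, layers = list(
    cont = matrix(rnorm(400, sd = 1e-12), 20, 20),
    cat = matrix(rep(c(0, 1), 200), 20, 20)))
  av <- availability_extent(r)
  pts <- sample_ipp_locations(c(0, 0), r, 200, av)
  fit <- suppressWarnings(
    fit_hier_rsf(pts, r, av, mcmc = mcmc_control(1500L, seed = 12)))
  ci <- apply(fit$mu_gamma, 2, quantile, c(0.025, 0.975))
  expect_true(ci[1, 2] < 0 && ci[2, 2] > 0)
})

test_that("more locations shrink the selection-coefficient posterior", {
  set.seed(56)
  r <- sim_test_raster(25, 25, 40, "moderate")
  av <- availability_extent(r)
  g <- c(1, 0.5)
  sdw <- function(n) {
    pts <- sample_ipp_locations(g, r, n, av)
    fit <- fit_hier_rsf(pts, r, av, mcmc = mcmc_control(1800L, seed = 13))
    mean(apply(fit$mu_gamma, 2, sd))
  }
  expect_lt(sdw(200), sdw(50))
})

test_that("hierarchical pooling across individuals recovers the population mean", {
  set.seed(57)
  r <- sim_test_raster(20, 20, 50, "high")
  av <- availability_extent(r)
  L <- 5
  locs <- lapply(1:L, function(l) {
    gl <- rnorm(2, c(1, 0.8), 0.3)
    sample_ipp_locations(gl, r, 120, av)
  })
  fit <- fit_hier_rsf(locs, r, av, mcmc = mcmc_control(2000L, seed = 14))
  mg <- apply(fit$mu_gamma, 2, median)
  expect_equal(mg, c(1, 0.8), tolerance = 0.5)
  expect_equal(dim(fit$gamma)[2], L)
  ## population covariance draws are positive definite
  expect_true(all(apply(fit$Sigma_gamma, 1, function(S) {
    all(eigen(matrix(S, 2, 2), symmetric = TRUE, only.values = TRUE)$values > 0)
  })))
})

test_that("joint ATM-RSF with gamma fixed at zero reduces to the plain ATM", {
  set.seed(58)
  r <- sim_test_raster(30, 30, 100, "moderate")  # 3 km x 3 km
  ctr <- c(1500, 1500)
  st <- generate_design(ctr, "encircle", 3)
  o <- simulate_relocation(ctr, st, 50); o$relocation <- 1
  f0 <- fit_atm_rsf(o, r, radius_r = 1500, gamma = c(0, 0),
                    kappa_model = kappa_fixed(50),
                    mcmc = mcmc_control(8000L, seed = 15))
  f1 <- fit_atm(o, radius_r = 1500, kappa_model = kappa_fixed(50),
                mcmc = mcmc_control(8000L, seed = 16))
  d0 <- location_draws(f0); d1 <- location_draws(f1)
  ## same support, but f0 additionally truncates to the raster extent;
  ## compare marginals on the common region
  keep1 <- d1[, 1] >= 0 & d1[, 1] <= 3000 & d1[, 2] >= 0 & d1[, 2] <= 3000
  t0 <- d0[seq(1, nrow(d0), by = 20), ]
  t1 <- d1[keep1, ][seq(1, sum(keep1), by = 20), ]
  expect_gt(suppressWarnings(ks.test(t0[, 1], t1[, 1])$p.value), 0.01)
  expect_gt(suppressWarnings(ks.test(t0[, 2], t1[, 2])$p.value), 0.01)
})

test_that("selection feedback tightens the location posterior", {
  ## strong selection for class-1 habitat whose boundary crosses the
  ## azimuth ray: knowing the selection surface should shrink location
  ## uncertainty relative to the plain ATM
  set.seed(59)
  catm <- matrix(0, 30, 30); catm[, 16:30] <- 1  # class 1 in the north
  r <- cov_raster(c(0, 0), 100, layers = list(
    cont = matrix(rnorm(900, sd = 1e-9), 30, 30), cat = catm))
  truth <- c(1500, 1520)
  st <- rbind(c(1500, 700))
  o <- data.frame(relocation = 1, x = st[, 1], y = st[, 2],
                  theta = expected_bearing(matrix(truth, 1, 2), st))
  f_atm <- fit_atm(o, radius_r = 1200, kappa_model = kappa_fixed(100),
                   mcmc = mcmc_control(6000L, seed = 17))
  f_rsf <- suppressWarnings(
    fit_atm_rsf(o, r, radius_r = 1200, gamma = c(0, 4),
                kappa_model = kappa_fixed(100),
                mcmc = mcmc_control(6000L, seed = 18)))
  disp <- function(d) sum(diag(cov(d)))
  expect_lt(disp(location_draws(f_rsf)), disp(location_draws(f_atm)))
})
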