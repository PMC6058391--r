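test_that("support region geometry: membership, area, sampler uniformity", {
  s1 <- support_region(matrix(c(0, 0), 1, 2), 100)
  expect_equal(support_area(s1), pi * 100^2)
  expect_true(in_support(s1, c(50, 50)))
  expect_false(in_support(s1, c(90, 90)))
  ## two disjoint circles
  s2 <- support_region(rbind(c(0, 0), c(500, 0)), 100)
  expect_equal(support_area(s2), 2 * pi * 100^2)
  ## two overlapping circles: lens formula vs grid integration
  s3 <- support_region(rbind(c(0, 0), c(120, 0)), 100)
  d <- 120; r <- 100
  lens <- 2 * r^2 * acos(d / (2 * r)) - d / 2 * sqrt(4 * r^2 - d^2)
  expect_equal(support_area(s3), 2 * pi * r^2 - lens, tolerance = 1e-9)
  expect_error(support_region(matrix(0, 1, 2), -5), "radius")
  ## sampler uniformity: chi-square GOF over an in-support partition
  set.seed(20)
  pts <- sample_support(s3, 1e5)
  expect_true(all(in_support(s3, pts)))
  qx <- cut(pts[, 1], quantile(pts[, 1], seq(0, 1, 0.25)),
            include.lowest = TRUE)
  qy <- cut(pts[, 2], quantile(pts[, 2], seq(0, 1, 0.25)),
            include.lowest = TRUE)
  ## counts in quantile cells of x crossed with sign(y) should match the
  ## cell areas; compare against an independent oracle sample
  oracle <- sample_support(s3, 1e5)
  tab1 <- table(cut(pts[, 1], seq(-100, 220, by = 40)), pts[, 2] > 0)
  tab2 <- table(cut(oracle[, 1], seq(-100, 220, by = 40)), oracle[, 2] > 0)
  expect_gt(suppressWarnings(chisq.test(cbind(c(tab1), c(tab2)))$p.value),
            0.01)
})

test_that("vanishing bearing noise recovers the true location", {
  set.seed(21)
  truth <- c(500, 300)
  phi <- c(0, pi / 2, pi, -pi / 2)
  st <- cbind(truth[1] + 600 * cos(phi), truth[2] + 600 * sin(phi))
  obs <- data.frame(relocation = 1, x = st[, 1], y = st[, 2],
                    theta = expected_bearing(matrix(truth, 1, 2), st))
  fit <- fit_atm(obs, radius_r = 1000, kappa_model = kappa_fixed(1e6),
                 mcmc = mcmc_control(3000L, seed = 1))
  expect_lt(sqrt(sum((colMeans(location_draws(fit)) - truth)^2)), 1)
})

test_that("single-azimuth posterior matches direct rejection sampling", {
  obs <- data.frame(relocation = 1, x = 0, y = 0, theta = pi / 4)
  fit <- fit_atm(obs, radius_r = 800, kappa_model = kappa_fixed(100),
                 mcmc = mcmc_control(22000L, burn_in = 2000L, seed = 2))
  dr <- location_draws(fit)
  sup <- support_region(matrix(c(0, 0), 1, 2), 800)
  expect_gte(mean(in_support(sup, dr)), 0.99)
  ## rejection-sampling oracle for the unnormalised posterior
  set.seed(3)
  cand <- sample_support(sup, 6e4)
  w <- exp(100 * (cos(pi / 4 - atan2(cand[, 2], cand[, 1])) - 1))
  orc <- cand[runif(nrow(cand)) < w, ]
  thin <- dr[seq(1, nrow(dr), by = 40), ]
  expect_gt(ks.test(thin[, 1], orc[, 1])$p.value, 0.01)
  expect_gt(ks.test(thin[, 2], orc[, 2])$p.value, 0.01)
})

test_that("every posterior draw respects the union-of-circles support", {
  set.seed(22)
  obs <- sim_azimuth_table(8, "random", 3, kappa = 25)
  fit <- fit_atm(obs, radius_r = 1000, kappa_model = kappa_homogeneous(),
                 mcmc = mcmc_control(1500L, seed = 4))
  for (i in 1:8) {
    expect_true(all(in_support(fit$support[[i]], location_draws(fit, i))))
  }
})

test_that("non-intersecting azimuths still give a proper posterior", {
  ## two parallel azimuths pointing east
  obs <- data.frame(relocation = 1, x = c(0, 0), y = c(0, 300),
                    theta = c(0, 0))
  fit <- fit_atm(obs, radius_r = 600, kappa_model = kappa_fixed(50),
                 mcmc = mcmc_control(4000L, seed = 5))
  dr <- location_draws(fit)
  expect_equal(nrow(dr), 3200)
  expect_true(all(is.finite(dr)))
  ## mass concentrates forward along the rays (x > 0 side)
  expect_gt(mean(dr[, 1] > 0), 0.9)
})

test_that("identical seed and configuration reproduce draws exactly", {
  set.seed(23)
  obs <- sim_azimuth_table(4, "encircle", 3, kappa = 50)
  f1 <- fit_atm(obs, radius_r = 1000, mcmc = mcmc_control(800L, seed = 7))
  f2 <- fit_atm(obs, radius_r = 1000, mcmc = mcmc_control(800L, seed = 7))
  expect_identical(f1$mu_draws, f2$mu_draws)
  expect_identical(f1$draws$log_kappa_shared, f2$draws$log_kappa_shared)
})

test_that("joint fitting shares concentration information across relocations", {
  ## a single azimuth fit alone vs jointly with many well-determined
  ## relocations: pooling kappa should shrink the lone location posterior
  set.seed(24)
  lone <- data.frame(x = 0, y = 0, theta = 0,
                     azimuth = math_to_compass(0), relocation = 999)
  many <- sim_azimuth_table(60, "encircle", 4, kappa = 400)
  joint <- rbind(lone, many)
  f_alone <- fit_atm(lone, radius_r = 800,
                     kappa_model = kappa_hier(~1),
                     mcmc = mcmc_control(4000L, seed = 8,
                                         store_kappa = FALSE))
  f_joint <- fit_atm(joint, radius_r = 800,
                     kappa_model = kappa_hier(~1),
                     mcmc = mcmc_control(4000L, seed = 8,
                                         store_kappa = FALSE))
  sd_alone <- mean(apply(location_draws(f_alone, 1), 2, sd))
  sd_joint <- mean(apply(location_draws(f_joint, 1), 2, sd))
  expect_lt(sd_joint, sd_alone)
})

test_that("degenerate inputs produce structured errors", {
  expect_error(fit_atm(data.frame()), "station|relocation|empty")
  obs <- data.frame(relocation = 1, x = 0, y = 0, theta = 0)
  expect_error(fit_atm(obs, radius_r = -5), "radius")
  ## rank-deficient design for the kappa hierarchy
  obs2 <- sim_azimuth_table(4, "random", 3, 50)
  obs2$z1 <- 1
  expect_error(fit_atm(obs2, radius_r = 1000,
                       kappa_model = kappa_hier(~z1 + I(2 * z1)),
                       mcmc = mcmc_control(200L)),
               "rank")
})

test_that("the distance effect on concentration is sampled and sane", {
  set.seed(28)
  M <- 40; J <- 4
  obs <- vector("list", M)
  for (i in seq_len(M)) {
    st <- generate_design(c(0, 0), "random", J)
    tt <- expected_bearing(matrix(c(0, 0), 1, 2), st)
    obs[[i]] <- data.frame(relocation = i, x = st[, 1], y = st[, 2],
                           theta = rvonmises(J, tt, exp(rnorm(J, 4.6, 0.5))))
  }
  ## data generated WITHOUT a distance effect: alpha1 must not hallucinate one
  fit <- fit_atm(do.call(rbind, obs), radius_r = 1000,
                 kappa_model = kappa_hier(~1, distance_effect = TRUE),
                 mcmc = mcmc_control(4000L, seed = 19, store_kappa = FALSE))
  a <- fit$draws$alpha1
  expect_true(!is.null(a) && all(is.finite(a)))
  ci <- quantile(a, c(0.025, 0.975))
  expect_true(ci[1] < 0 && ci[2] > 0)
  expect_lt(abs(median(a)), 0.5)
  ## strong negative distance effect: the posterior leans negative
  set.seed(31)
  obs2 <- vector("list", 100)
  for (i in 1:100) {
    st <- generate_design(c(0, 0), "random", 4,
                          function(n) runif(n, 50, 2000))
    d <- sqrt(rowSums(st^2))
    tt <- expected_bearing(matrix(c(0, 0), 1, 2), st)
    obs2[[i]] <- data.frame(relocation = i, x = st[, 1], y = st[, 2],
                            theta = rvonmises(4, tt,
                                              exp(rnorm(4, 12 - 1.5 * log(d), 0.3))))
  }
  fit2 <- fit_atm(do.call(rbind, obs2), radius_r = 2200,
                  kappa_model = kappa_hier(~1, distance_effect = TRUE,
                                           sigma2_beta = 25, alpha1_var = 4),
                  mcmc = mcmc_control(12000L, seed = 6, store_kappa = FALSE,
                                      thin = 5))
  expect_lt(median(fit2$draws$alpha1), 0)
})

test_that("HPD regions match the closed-form normal area and nest", {
  set.seed(25)
  S <- matrix(c(9, 2, 2, 4), 2, 2)
  z <- matrix(rnorm(8000), ncol = 2) %*% chol(S)
  r95 <- hpd_region(z, 0.95, max_draws = 2000)
  a95 <- hpd_area(r95, n_grid = 150)
  expect_equal(a95, pi * qchisq(0.95, 2) * sqrt(det(S)), tolerance = 0.08)
  ## nesting: every draw inside the 50% region is inside the 95% region
  r50 <- hpd_region(z, 0.50, max_draws = 2000)
  sub <- z[1:500, ]
  in50 <- hpd_contains(r50, sub)
  in95 <- hpd_contains(r95, sub)
  expect_true(all(in95[in50]))
  expect_gt(r50$threshold, r95$threshold)
  ## area grows with level
  expect_lt(hpd_area(r50, 120), a95)
  ## degenerate posterior collapses to a point region
  zz <- matrix(rep(c(3, 4), each = 50), ncol = 2)
  rd <- hpd_region(zz, 0.95)
  expect_true(rd$degenerate)
  expect_true(hpd_contains(rd, c(3, 4)))
  expect_false(hpd_contains(rd, c(3.1, 4)))
})

test_that("hpd polygons are closed rings around the mass", {
  set.seed(26)
  z <- matrix(rnorm(2000), ncol = 2)
  r <- hpd_region(z, 0.9)
  polys <- hpd_polygon(r)
  expect_gt(length(polys), 0)
  for (p in polys) expect_equal(p[1, ], p[nrow(p), ])
})

test_that("effective size detects autocorrelation", {
  set.seed(27)
  iid <- rnorm(2000)
  ar <- as.numeric(arima.sim(list(ar = 0.9), 2000))
  expect_gt(effective_size(iid), 1200)
  expect_lt(effective_size(ar), effective_size(iid) / 3)
})
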