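test_that("intersection average matches pairwise enumeration", {
  ## worked example: south/south pair is parallel and dropped
  st <- rbind(c(0, 0), c(2, 2), c(4, 2))
  b <- c(0, -pi / 2, -pi / 2)
  expect_equal(intersection_average(st, b), c(3, 0))
  ## two azimuths: the single forward intersection exactly
  expect_equal(intersection_average(rbind(c(0, 0), c(2, 2)), c(0, -pi / 2)),
               c(2, 0))
  expect_error(intersection_average(matrix(c(0, 0), 1, 2), 0), ">= 2")
  ## brute-force oracle over random 4-azimuth sets
  set.seed(10)
  for (k in 1:100) {
    s <- sim_triangulation(4, kappa = 20)
    got <- intersection_average(s$stations, s$bearings,
                                fallback_to_lines = FALSE)
    pts <- NULL
    for (i in 1:3) for (j in (i + 1):4) {
      p <- ray_intersection(s$stations[i, ], s$bearings[i],
                            s$stations[j, ], s$bearings[j])
      if (!is.null(p)) pts <- rbind(pts, p)
    }
    if (is.null(pts)) expect_null(got) else
      expect_equal(got, unname(colMeans(pts)), tolerance = 1e-12)
  }
})

test_that("triangulation satisfies the gradient and grid-search oracles", {
  set.seed(11)
  n_checked <- 0L
  for (k in 1:200) {
    s <- sim_triangulation(sample(3:5, 1), kappa = 50)
    fit <- triangulate(s$stations, s$bearings, method = "mle-fixed-point")
    if (!fit$converged) next
    n_checked <- n_checked + 1L
    g <- triang_gradient(s$stations, s$bearings, fit$estimate)
    expect_lt(sqrt(sum(g^2)), 1e-6)
    ## no node of a 1 m lattice beats the returned optimum (local window)
    if (k <= 25) {
      obj <- function(m) {
        tt <- expected_bearing(matrix(m, 1, 2), s$stations)
        sum(1 - cos(wrap_radians(s$bearings - tt)))
      }
      lat <- as.matrix(expand.grid(fit$estimate[1] + (-25:25),
                                   fit$estimate[2] + (-25:25)))
      vals <- apply(lat, 1, obj)
      expect_gte(min(vals), obj(fit$estimate) - 1e-10)
    }
  }
  expect_gt(n_checked, 180)  # failures are rare at kappa = 50
})

test_that("two intersecting azimuths are fit exactly by every method", {
  st <- rbind(c(0, 0), c(2, 2))
  b <- c(0, -pi / 2)
  for (m in c("mle-fixed-point", "huber", "andrews", "mle-quasi-newton")) {
    f <- triangulate(st, b, method = m)
    expect_true(f$converged)
    expect_equal(f$estimate, c(2, 0), tolerance = 1e-4)
    expect_false(f$cov_ok)  # no covariance from two azimuths
  }
})

test_that("Huber with an enormous tuning constant reduces to the MLE", {
  set.seed(12)
  for (k in 1:20) {
    s <- sim_triangulation(4, kappa = 30)
    f1 <- triangulate(s$stations, s$bearings, method = "mle-fixed-point")
    f2 <- triangulate(s$stations, s$bearings, method = "huber",
                      tuning_c = 1e9)
    if (f1$converged && f2$converged) {
      expect_equal(f1$estimate, f2$estimate, tolerance = 1e-6)
    }
  }
})

test_that("fixed-point and quasi-Newton agree on well-conditioned problems", {
  set.seed(13)
  agree <- 0L; both <- 0L
  for (k in 1:40) {
    s <- sim_triangulation(4, kappa = 100)
    f1 <- triangulate(s$stations, s$bearings, method = "mle-fixed-point")
    f2 <- triangulate(s$stations, s$bearings, method = "mle-quasi-newton")
    if (f1$converged && f2$converged) {
      both <- both + 1L
      if (sqrt(sum((f1$estimate - f2$estimate)^2)) < 0.1) agree <- agree + 1L
    }
  }
  expect_gt(both, 30)
  expect_gte(agree / both, 0.95)
})

test_that("estimates are equivariant under translation and rotation", {
  set.seed(14)
  s <- sim_triangulation(4, kappa = 50)
  f0 <- triangulate(s$stations, s$bearings, method = "mle-fixed-point")
  ## translation
  sh <- c(1234.5, -987.6)
  f1 <- triangulate(sweep(s$stations, 2, -sh), s$bearings,
                    method = "mle-fixed-point")
  expect_equal(f1$estimate, f0$estimate + sh, tolerance = 1e-5)
  ## rotation of the frame
  a <- 0.73
  Rm <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  f2 <- triangulate(s$stations %*% t(Rm), wrap_radians(s$bearings + a),
                    method = "mle-fixed-point")
  expect_equal(f2$estimate, drop(Rm %*% f0$estimate), tolerance = 1e-5)
})

test_that("parallel azimuths fail structurally rather than raising", {
  st <- rbind(c(0, 0), c(0, 100), c(0, 200))
  f <- triangulate(st, c(0, 0, 0), method = "mle-fixed-point")
  expect_false(f$converged)
  expect_s3_class(f, "triangulation_fit")
})

test_that("confidence ellipses have the chi-square geometry and coverage", {
  ## identity covariance: circle of radius sqrt(chisq quantile)
  fit <- list(estimate = c(0, 0), covariance = diag(2))
  el <- confidence_ellipse(fit, 0.95)
  expect_equal(el$semi_axes, rep(sqrt(qchisq(0.95, 2)), 2))
  expect_equal(el$area, pi * qchisq(0.95, 2))
  ## area formula for random covariances
  set.seed(15)
  for (k in 1:20) {
    A <- matrix(rnorm(4), 2, 2)
    S <- crossprod(A) + diag(0.1, 2)
    el <- confidence_ellipse(list(estimate = c(1, 2), covariance = S), 0.9)
    expect_equal(el$area, pi * qchisq(0.9, 2) * sqrt(det(S)),
                 tolerance = 1e-10)
    expect_equal(polygon_area(ellipse_polygon(el, 2000)), el$area,
                 tolerance = 1e-4 * el$area)
  }
  ## Monte-Carlo containment oracle
  set.seed(16)
  S <- matrix(c(4, 1.5, 1.5, 2), 2, 2)
  L <- chol(S)
  z <- matrix(rnorm(2e5), ncol = 2) %*% L
  el <- confidence_ellipse(list(estimate = c(0, 0), covariance = S), 0.95)
  inside <- mahalanobis(z, c(0, 0), S) <= qchisq(0.95, 2)
  expect_equal(mean(inside), 0.95, tolerance = 0.005)
  expect_equal(mean(vapply(seq_len(5e3), function(i) {
    ellipse_contains(el, z[i, ])
  }, logical(1))), 0.95, tolerance = 0.02)
  expect_error(confidence_ellipse(list(estimate = c(0, 0),
                                       covariance = matrix(0, 2, 2))))
})
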