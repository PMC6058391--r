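## Shared fixtures for the test suite: everything is generated in code.

## random triangulation problem: stations around a true location at the
## origin, bearings von Mises with concentration kappa
sim_triangulation <- function(n_theta = 3L, kappa = 50,
                              dmin = 100, dmax = 1000) {
  phi <- runif(n_theta, -pi, pi)
  d <- runif(n_theta, dmin, dmax)
  st <- cbind(d * cos(phi), d * sin(phi))
  th <- rvonmises(n_theta, expected_bearing(matrix(c(0, 0), 1, 2), st), kappa)
  list(stations = st, bearings = th, truth = c(0, 0))
}

## azimuth table for M relocations under a named design
sim_azimuth_table <- function(M, design = "random", n_theta = 3L,
                              kappa = 100) {
  obs <- vector("list", M)
  for (i in seq_len(M)) {
    st <- generate_design(c(0, 0), design, n_theta)
    o <- simulate_relocation(c(0, 0), st, kappa)
    o$relocation <- i
    obs[[i]] <- o
  }
  do.call(rbind, obs)
}

## numerical gradient of the von Mises triangulation objective
triang_gradient <- function(stations, bearings, mu, h = 1e-4) {
  obj <- function(m) {
    tt <- expected_bearing(matrix(m, 1, 2), stations)
    sum(1 - cos(wrap_radians(bearings - tt)))
  }
  c((obj(mu + c(h, 0)) - obj(mu - c(h, 0))) / (2 * h),
    (obj(mu + c(0, h)) - obj(mu - c(0, h))) / (2 * h))
}

## small test raster with deterministic-ish layers
sim_test_raster <- function(nx = 20L, ny = 20L, cellsize = 50,
                            autocorrelation = "moderate") {
  simulate_grf_covariates(nx, ny, cellsize, autocorrelation)
}
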