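test_that("ground-truth model conserves mass and carries the right fractions", {
  m <- wt_like_model()
  expect_s3_class(m, "photocycle_model")
  expect_equal(sum(m$scheme$initial), 1)
  expect_equal(m$conductive_fraction, 0.51)
  sol <- eigen_solve(build_kinetic_matrix(m$scheme))
  ev <- time_evolution(sol, oracle_times())
  expect_equal(rowSums(ev$concentrations), rep(1, 25), tolerance = 1e-12)
})

test_that("default opening rate is degenerate with the third apparent rate", {
  m <- wt_like_model()
  k_open <- m$scheme$transitions$rate[m$scheme$transitions$from == "K1"]
  sol2 <- eigen_solve(build_kinetic_matrix(m$cycles$cycle2))
  lam3 <- sort(abs(sol2$eigenvalues), decreasing = TRUE)[3]
  expect_equal(k_open, lam3, tolerance = 1e-12)
  # the combined model therefore shows exactly five observable lifetimes
  sol <- eigen_solve(build_kinetic_matrix(m$scheme))
  bs <- compute_b_spectra(m$basis, sol, m$mapping)
  nz <- attr(bs, "eigenvalues") != 0
  expect_equal(sum(nz), 5)
  # an explicit, well-separated opening rate instead yields a sixth one
  m6 <- wt_like_model(k_open = 3333)
  sol6 <- eigen_solve(build_kinetic_matrix(m6$scheme))
  bs6 <- compute_b_spectra(m6$basis, sol6, m6$mapping)
  expect_equal(sum(attr(bs6, "eigenvalues") != 0), 6)
})

test_that("noiseless data are exactly basis times form concentrations", {
  m <- wt_like_model()
  t <- oracle_times()
  ds <- simulate_absorbance(m, t)
  sol <- eigen_solve(build_kinetic_matrix(m$scheme))
  ev <- time_evolution(sol, t)
  forms <- colnames(m$basis$E)
  Cf <- vapply(forms, function(f) {
    cols <- names(m$mapping)[m$mapping == f]
    rowSums(ev$concentrations[, cols, drop = FALSE])
  }, numeric(length(t)))
  expect_equal(ds$D, m$basis$E %*% t(Cf), ignore_attr = TRUE)
})

test_that("noise is reproducible by seed and has the requested scale", {
  m <- wt_like_model()
  t <- oracle_times()
  d1 <- simulate_absorbance(m, t, noise_sd = 0.01, seed = 7)
  d2 <- simulate_absorbance(m, t, noise_sd = 0.01, seed = 7)
  d3 <- simulate_absorbance(m, t, noise_sd = 0.01, seed = 8)
  expect_identical(d1$D, d2$D)
  expect_false(identical(d1$D, d3$D))
  d0 <- simulate_absorbance(m, t)
  expect_equal(sd(d1$D - d0$D), 0.01, tolerance = 0.05)
  expect_error(simulate_absorbance(m, t, noise_sd = 0.01), "seed")
})

test_that("seeded simulation does not disturb the caller's RNG stream", {
  set.seed(42)
  before <- runif(1)
  set.seed(42)
  invisible(simulate_absorbance(wt_like_model(), oracle_times(),
                                noise_sd = 0.01, seed = 5))
  expect_identical(runif(1), before)
})

test_that("photocurrent follows the summed conductive populations", {
  m <- wt_like_model()
  sol <- eigen_solve(build_kinetic_matrix(m$scheme))
  t <- default_times()
  ev <- time_evolution(sol, t)
  tr <- simulate_current(ev, m$scheme$conductive)
  expect_equal(tr$current,
               ev$concentrations[, "O1"] + ev$concentrations[, "O2"])
  expect_lte(max(tr$current), m$conductive_fraction)
  # rises from ~0 and decays back to ~0
  expect_lt(tr$current[1], 0.01)
  expect_lt(tr$current[length(t)], 0.02)
  expect_gt(max(tr$current), 0.3)
  # no conductive states -> zero current
  tr0 <- simulate_current(ev, character(0))
  expect_identical(tr0$current, numeric(length(t)))
})

test_that("dataset CSV + JSON sidecar round trip preserves the data", {
  m <- wt_like_model()
  ds <- simulate_absorbance(m, oracle_times(), noise_sd = 0.002, seed = 3)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ds.csv")
  write_dataset_csv(ds, path)
  back <- read_dataset_csv(path)
  expect_equal(back$D, ds$D, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(back$times, ds$times)
  expect_equal(back$grid$wavelength, ds$grid$wavelength)
})

test_that("model parameter validation rejects inconsistent fractions", {
  expect_error(wt_like_model(conductive = 0.51, o2_fraction = 0.6))
  expect_error(wt_like_model(n1_products = c(N2 = 0.3, M = 0.3, Rearly = 0.3)))
})
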