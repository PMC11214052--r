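# a small noiseless data matrix with known lifetimes and amplitude spectra
make_exp_dataset <- function(taus, times = default_times(1e-6, 1, 120)) {
  basis <- default_basis()
  n <- length(taus)
  B <- basis$E[, seq_len(n + 1), drop = FALSE]   # amplitudes + constant term
  X <- cbind(exp(-outer(times, 1 / taus)), 1)
  list(D = B %*% t(X), B = B, times = times, taus = taus)
}

test_that("SVD rank counts the independent spectral forms", {
  m <- wt_like_model()
  ds <- simulate_absorbance(m, default_times())
  expect_equal(as.integer(svd_rank(ds)), 4)
  sv <- attr(svd_rank(ds), "singular_values")
  expect_gt(sv[4] / sv[5], 1e4)
  # two-form data have rank 2
  d2 <- make_exp_dataset(1e-3)
  expect_equal(as.integer(svd_rank(d2$D)), 2)
})

test_that("global fit recovers known lifetimes and amplitudes exactly", {
  taus <- c(2e-5, 1.3e-3, 8e-2)
  d <- make_exp_dataset(taus)
  fit <- global_exp_fit(d$D, 3, times = d$times, n_starts = 4)
  expect_equal(fit$lifetimes, taus, tolerance = 1e-6)
  expect_equal(unname(fit$b_spectra), unname(d$B), tolerance = 1e-5)
  expect_lt(fit$fit_residual, 1e-8)
})

test_that("global fit works from jittered starts without the true values", {
  taus <- c(1e-4, 1e-2)
  d <- make_exp_dataset(taus)
  fit <- global_exp_fit(d$D, 2, times = d$times, n_starts = 6, seed = 2)
  expect_equal(fit$lifetimes, taus, tolerance = 1e-5)
})

test_that("a too-short time window is refused upfront", {
  d <- make_exp_dataset(1e-3, times = seq(1e-3, 1e-2, length.out = 40))
  expect_error(global_exp_fit(d$D, 3, times = d$times), "time span too short")
})

test_that("nearly duplicate fitted lifetimes raise a warning", {
  d <- make_exp_dataset(c(1e-3, 1.4e-3))
  expect_warning(global_exp_fit(d$D, 2, times = d$times, n_starts = 6),
                 "duplicate")
})

test_that("sequential spectra invert the Bateman chain built from the fit", {
  # forward-construct a sequential chain with known spectra, then recover
  basis <- default_basis()
  k <- c(2e4, 6e2, 25)
  states <- sprintf("In%d", 1:4)
  chain <- kinetic_scheme(states,
                          data.frame(from = states[1:3], to = states[2:4],
                                     rate = k),
                          initial = c(In1 = 1))
  sol <- eigen_solve(build_kinetic_matrix(chain))
  S_true <- basis$E               # each intermediate one pure form
  times <- default_times(1e-6, 1, 150)
  conc <- time_evolution(sol, times)$concentrations
  D <- S_true %*% t(conc)
  fit <- global_exp_fit(D, 3, times = times, n_starts = 4)
  seq_sp <- sequential_from_b(fit)
  expect_equal(unname(seq_sp$spectra), unname(S_true), tolerance = 1e-4)
})

test_that("sequential conversion refuses unsorted or near-equal rates", {
  d <- make_exp_dataset(c(1e-4, 1e-2))
  fit <- global_exp_fit(d$D, 2, times = d$times, n_starts = 4)
  bad <- fit
  bad$lifetimes <- rev(bad$lifetimes)
  expect_error(sequential_from_b(bad), "ascending")
  close <- fit
  close$lifetimes <- c(1e-3, 1.0000001e-3)
  # rates this close inflate the Bateman condition number to ~1e7
  expect_error(
    suppressWarnings(sequential_from_b(close, max_condition = 1e6)),
    "condition")
})

test_that("composition deconvolution returns the exact form fractions", {
  basis <- default_basis()
  frac <- cbind(In1 = c(1, 0, 0, 0), In2 = c(0.51, 0.49, 0, 0),
                In3 = c(0.14, 0.19, 0.10, 0.57))
  rownames(frac) <- colnames(basis$E)
  S <- basis$E %*% frac
  comp <- deconvolve_composition(S, basis)
  expect_equal(comp$fractions, frac, tolerance = 1e-8)
  expect_true(all(abs(colSums(comp$fractions) - 1) < 1e-9))
  expect_lt(max(attr(comp, "residuals")), 1e-10)
})

test_that("nonnegativity is enforced in the deconvolution", {
  basis <- default_basis()
  # a spectrum outside the cone of the basis: negative of one form
  S <- cbind(-basis$E[, "M"] + basis$E[, "R"])
  comp <- deconvolve_composition(S, basis, normalize = FALSE)
  expect_true(all(comp$fractions >= 0))
})

test_that("composition matrix constructor validates and labels", {
  M <- matrix(0.25, 4, 6)
  cm <- composition_matrix(M)
  expect_identical(rownames(cm$fractions), c("K-like", "L-like", "M", "R"))
  expect_identical(colnames(cm$fractions), sprintf("In%d", 1:6))
  expect_error(composition_matrix(matrix(-1, 4, 6)))
})

test_that("composition CSV round trip preserves the fractions", {
  comp <- composition_matrix(matrix(runif(24), 4, 6))
  path <- file.path(withr::local_tempdir(), "comp.csv")
  write_composition_csv(comp, path)
  df <- read.csv(path, check.names = FALSE)
  expect_equal(as.matrix(df[, -1]), comp$fractions, ignore_attr = TRUE,
               tolerance = 1e-12)
})
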