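test_that("scheme construction validates states, rates and populations", {
  expect_error(kinetic_scheme(c("A", "B"),
                              data.frame(from = "A", to = "C", rate = 1),
                              initial = c(A = 1)),
               "unknown state")
  expect_error(kinetic_scheme(c("A", "B"),
                              data.frame(from = "A", to = "B", rate = -2),
                              initial = c(A = 1)),
               "positive")
  expect_error(kinetic_scheme(c("A", "B"),
                              data.frame(from = "A", to = "B", rate = 1),
                              initial = c(A = -0.1)),
               "nonnegative")
  expect_error(kinetic_scheme(c("A", "A"),
                              data.frame(from = "A", to = "A", rate = 1),
                              initial = c(A = 1)))
})

test_that("rate matrix columns sum to zero (mass conservation)", {
  sch <- random_acyclic_scheme(6)
  A <- build_kinetic_matrix(sch)
  expect_lt(max(abs(colSums(unclass(A)))), 1e-9 * max(abs(A)))
  offdiag <- unclass(A); diag(offdiag) <- 0
  expect_true(all(offdiag >= 0))
})

test_that("two-state eigen solution matches the closed form", {
  k <- 3210
  sch <- kinetic_scheme(c("K", "O"),
                        data.frame(from = "K", to = "O", rate = k),
                        initial = c(K = 1))
  sol <- eigen_solve(build_kinetic_matrix(sch))
  t <- oracle_times()
  ev <- time_evolution(sol, t)
  expect_equal(ev$concentrations[, "K"], exp(-k * t), tolerance = 1e-12)
  expect_equal(ev$concentrations[, "O"], 1 - exp(-k * t), tolerance = 1e-12)
})

test_that("three-state chain matches the Bateman closed form", {
  a <- 5e4; b <- 700
  sch <- kinetic_scheme(c("X", "Y", "Z"),
                        data.frame(from = c("X", "Y"), to = c("Y", "Z"),
                                   rate = c(a, b)),
                        initial = c(X = 1))
  sol <- eigen_solve(build_kinetic_matrix(sch))
  t <- oracle_times()
  ev <- time_evolution(sol, t)
  y <- a / (b - a) * (exp(-a * t) - exp(-b * t))
  expect_equal(ev$concentrations[, "Y"], y, tolerance = 1e-10)
  expect_equal(rowSums(ev$concentrations), rep(1, length(t)),
               tolerance = 1e-12)
})

test_that("eigenvalues come out fastest first with the zero mode last", {
  sol <- solve_scheme(random_acyclic_scheme(7))
  ev <- sol$eigenvalues
  expect_false(is.unsorted(rev(abs(ev))))
  expect_identical(ev[length(ev)], 0)
  expect_true(all(ev <= 0))
})

test_that("parallel cycles sharing rates produce grouped degenerate modes", {
  m <- wt_like_model()
  sol <- eigen_solve(build_kinetic_matrix(m$scheme))
  sizes <- lengths(sol$degeneracy_groups)
  expect_equal(sum(sizes), length(m$scheme$states))
  # opening/third-rate pair, early-ms pair, late-ms triple, two zero modes
  expect_true(any(sizes >= 3))
  expect_equal(sum(sizes > 1), 4)
})

test_that("irreversible loops with complex spectra are rejected", {
  sch <- kinetic_scheme(c("A", "B", "C"),
                        data.frame(from = c("A", "B", "C"),
                                   to = c("B", "C", "A"),
                                   rate = c(10, 10, 10)),
                        initial = c(A = 1))
  expect_error(eigen_solve(build_kinetic_matrix(sch)), "complex eigenvalues")
})

test_that("defective (Jordan-block) matrices are diagnosed by eigenvalue", {
  sch <- kinetic_scheme(c("A", "B", "C"),
                        data.frame(from = c("A", "B"), to = c("B", "C"),
                                   rate = c(100, 100)),
                        initial = c(A = 1))
  expect_error(eigen_solve(build_kinetic_matrix(sch)), "defective")
})

test_that("near-degenerate but distinct rates raise a warning", {
  sch <- kinetic_scheme(c("A", "B", "C"),
                        data.frame(from = c("A", "B"), to = c("B", "C"),
                                   rate = c(100, 100 * (1 + 1e-7))),
                        initial = c(A = 1))
  expect_warning(eigen_solve(build_kinetic_matrix(sch)), "near-degenerate")
})

test_that("time evolution matches the matrix-exponential oracle", {
  m <- wt_like_model()
  A <- build_kinetic_matrix(m$scheme)
  sol <- eigen_solve(A)
  t <- oracle_times()
  ours <- time_evolution(sol, t)$concentrations
  ref <- expm_evolution(A, sol$c0, t)
  expect_lt(max(abs(ours - ref)), 1e-9)
})

test_that("transitions between isospectral states are spectrally silent", {
  basis <- default_basis()
  sch <- kinetic_scheme(c("K", "O"),
                        data.frame(from = "K", to = "O", rate = 3333),
                        conductive = "O", initial = c(K = 1))
  sol <- eigen_solve(build_kinetic_matrix(sch))
  bs <- compute_b_spectra(basis, sol, c(K = "K-like", O = "K-like"))
  norms <- sqrt(colSums(bs^2))
  ev <- attr(bs, "eigenvalues")
  expect_lt(norms[ev != 0], 1e-12 * norms[ev == 0])
})

test_that("b-spectra combine degenerate groups and label eigenvalues", {
  m <- wt_like_model()
  sol <- eigen_solve(build_kinetic_matrix(m$scheme))
  bs <- compute_b_spectra(m$basis, sol, m$mapping)
  expect_equal(ncol(bs), length(sol$degeneracy_groups))
  expect_length(attr(bs, "eigenvalues"), ncol(bs))
  expect_error(compute_b_spectra(m$basis, sol, m$mapping[-1]), "unmapped")
})

test_that("branch rates sum exactly and follow the yield proportions", {
  k <- branch_rates(500, c(N2 = 0.19, M = 0.10, R = 0.20))
  expect_identical(sum(k), 500)
  expect_equal(k[["N2"]] / k[["M"]], 1.9, tolerance = 1e-12)
  expect_error(branch_rates(500, c(-0.1, 0.2)), "nonnegative")
  expect_error(branch_rates(500, c(0, 0)), "positive")
})

test_that("scheme JSON round trip is bit exact", {
  sch <- random_reversible_tree(5)
  path <- file.path(withr::local_tempdir(), "scheme.json")
  scheme_to_json(sch, path)
  back <- scheme_from_json(path)
  expect_identical(back$states, sch$states)
  expect_identical(back$transitions$rate, sch$transitions$rate)
  expect_equal(back$initial, sch$initial)
})

test_that("combining cycles requires disjoint labels and stacks blocks", {
  s1 <- kinetic_scheme("A", NULL, initial = c(A = 0.4))
  s2 <- kinetic_scheme(c("B", "C"),
                       data.frame(from = "B", to = "C", rate = 5),
                       initial = c(B = 0.6))
  both <- combine_schemes(s1, s2)
  expect_identical(both$states, c("A", "B", "C"))
  expect_equal(sum(both$initial), 1)
  expect_error(combine_schemes(s1, s1), "disjoint")
})
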