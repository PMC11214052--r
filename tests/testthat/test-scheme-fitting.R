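test_that("topology instantiation places rates and shares constrained slots", {
  topo <- photokin:::topo_cycle1_branching()
  expect_true("k_open" %in% names(topo$fixed))
  fs <- free_slots(topo)
  expect_false("k_open" %in% fs)
  rates <- setNames(c(70, 30, 20, 5, 8), fs)
  sch <- instantiate_topology(topo, c(rates, k_open = 8745))
  tr <- sch$transitions
  # every transition labelled k_slow carries one shared value
  slow <- tr$rate[topo$transitions$slot == "k_slow"]
  expect_true(all(slow == rates[["k_slow"]]))
  expect_equal(tr$rate[topo$transitions$slot == "k_open"], 8745)
  expect_error(instantiate_topology(topo, rates), "left unset")
  expect_error(instantiate_topology(topo, rates[-1]), "no rate for slot")
})

test_that("b_matrix labels fitted spectra with signed eigenvalues", {
  d_taus <- c(1e-4, 1e-2)
  basis <- default_basis()
  B <- basis$E[, 1:3]
  times <- default_times(1e-6, 1, 100)
  D <- B %*% t(cbind(exp(-outer(times, 1 / d_taus)), 1))
  fit <- global_exp_fit(D, 2, times = times, n_starts = 4)
  bm <- b_matrix(fit)
  ev <- attr(bm, "eigenvalues")
  expect_equal(ev[3], 0)
  expect_equal(ev[1:2], -1 / fit$lifetimes)
})

test_that("subtracting the conductive cycle leaves the nonconductive spectra", {
  m <- wt_like_model()
  sol <- eigen_solve(build_kinetic_matrix(m$scheme))
  bs_tot <- compute_b_spectra(m$basis, sol, m$mapping)
  sol1 <- eigen_solve(build_kinetic_matrix(m$cycles$cycle1))
  bsf <- cycle2_target_b(bs_tot, sol1, m$basis, m$mapping)
  sol2 <- eigen_solve(build_kinetic_matrix(m$cycles$cycle2))
  bs2 <- compute_b_spectra(m$basis, sol2, m$mapping)
  ev_f <- attr(bsf, "eigenvalues")
  ev_2 <- attr(bs2, "eigenvalues")
  for (j in seq_along(ev_2)) {
    k <- if (ev_2[j] == 0) which(ev_f == 0) else
      which(abs(ev_f - ev_2[j]) < 1e-6 * abs(ev_2[j]))
    expect_length(k, 1)
    expect_lt(max(abs(bsf[, k] - bs2[, j])), 1e-9)
  }
})

test_that("an unmatched visible cycle-1 component is a reported error", {
  m <- wt_like_model(k_open = 3333)    # isolated opening eigenvalue
  sol1 <- eigen_solve(build_kinetic_matrix(m$cycles$cycle1))
  # targets deliberately missing the 3333 s^-1 component
  bs_stub <- matrix(0, nrow(m$basis$E), 3)
  attr(bs_stub, "eigenvalues") <- c(-500, -10, 0)
  expect_error(cycle2_target_b(bs_stub, sol1, m$basis, m$mapping),
               "degeneracy-group mismatch")
})

test_that("rate fitting recovers the generating rates of a branching scheme", {
  basis <- default_basis()
  topo <- photokin:::topo_cycle1_branching(initial = c(K = 0.51))
  true_rates <- c(k_o1_o2 = 137, k_o1_m = 98, k_o1_n2 = 190, k_o1_r = 75,
                  k_slow = 10)
  sch <- instantiate_topology(topo, c(true_rates, k_open = 8745))
  sol <- eigen_solve(build_kinetic_matrix(sch))
  target_b <- compute_b_spectra(basis, sol, topo$mapping)
  targets <- sort(unique(abs(sol$eigenvalues[sol$eigenvalues != 0])),
                  decreasing = TRUE)
  fit <- fit_scheme_rates(topo, target_rates = targets, target_b = target_b,
                          basis = basis, fixed_rates = c(k_open = 8745),
                          n_starts = 6, seed = 4,
                          start_center = true_rates * 2)
  expect_true(fit$success)
  expect_equal(fit$free[names(true_rates)], true_rates, tolerance = 1e-3)
  expect_lt(fit$b_residual, 1e-4)
})

test_that("the accept predicate discards disallowed labelings", {
  basis <- default_basis()
  topo <- photokin:::topo_cycle1_branching(initial = c(K = 0.51))
  true_rates <- c(k_o1_o2 = 137, k_o1_m = 98, k_o1_n2 = 190, k_o1_r = 75,
                  k_slow = 10)
  sch <- instantiate_topology(topo, c(true_rates, k_open = 8745))
  sol <- eigen_solve(build_kinetic_matrix(sch))
  targets <- sort(unique(abs(sol$eigenvalues[sol$eigenvalues != 0])),
                  decreasing = TRUE)
  expect_error(
    fit_scheme_rates(topo, target_rates = targets,
                     fixed_rates = c(k_open = 8745), n_starts = 2, seed = 1,
                     accept = function(r) FALSE),
    "labeling convention")
})

test_that("a rate with no influence on the data is flagged unidentifiable", {
  # a free slot draining an unpopulated state cannot move the objective
  topo <- scheme_topology(
    "dangling", c("A", "B", "X"),
    data.frame(from = c("A", "X"), to = c("B", "B"),
               slot = c("k_ab", "k_xb")),
    mapping = c(A = "K-like", B = "R", X = "M"),
    initial = c(A = 1))
  fit <- fit_scheme_rates(topo, target_rates = 100, n_starts = 4, seed = 1)
  expect_false(fit$identifiability$identifiable)
  expect_true("k_xb" %in% rownames(fit$identifiability$null_directions))
})

test_that("the topology catalog prunes per condition", {
  generic <- topology_catalog()
  expect_true(all(c("cycle1_branching_general", "cycle2_equilibrium")
                  %in% names(generic)))
  # WT at pH 5.5 has no M state anywhere
  no_m <- topology_catalog("wt_ph55")
  states <- unlist(lapply(no_m[c("cycle1_branching_general",
                                 "cycle2_branching_general")],
                          `[[`, "states"))
  expect_false("M" %in% states)
  # D234N keeps M but drops the fast direct recovery branches
  d234n <- topology_catalog("d234n_ph74")
  slots <- d234n$cycle1_branching_general$transitions$slot
  expect_false("k_o1_r" %in% slots)
  expect_true("k_l2m1" %in% d234n$cycle2_branching_general$transitions$slot)
  # the acidic S97E case is the dedicated triple-cycle template
  s97e <- topology_catalog("s97e_ph56")
  expect_identical(names(s97e), "s97e_lowpH_triple")
  expect_false(s97e$s97e_lowpH_triple$conductive == "O1")
  expect_warning(topology_catalog("nonsense"), "unknown condition")
})

test_that("pattern-class comparison reports equivalence and the verdict", {
  f <- function(cls, obj) list(topology = list(pattern_class = cls),
                               objective = obj)
  rep2 <- classify_equilibrium_vs_branching(
    list(f("branching", 1e-6), f("equilibrium", 1.4e-6)))
  expect_true(rep2$equivalent)
  expect_match(rep2$verdict, "mechanistically rejected")
  rep1 <- classify_equilibrium_vs_branching(list(f("branching", 1e-6)))
  expect_true(is.na(rep1$equivalent))
  expect_match(rep1$note, "comparison missing")
  expect_error(classify_equilibrium_vs_branching(list()), "no fit results")
})
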