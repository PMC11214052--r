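wt74 <- gtacr1_fractions("wt_ph74")

test_that("the fraction table covers all conditions and rejects unknowns", {
  tab <- gtacr1_fractions()
  expect_setequal(names(tab),
                  c("wt_ph74", "wt_ph55", "wt_ph85", "a75e_ph74",
                    "d234n_ph74", "d234n_ph45", "s97e_ph74", "s97e_ph56"))
  expect_error(gtacr1_fractions("wt_ph60"), "unknown condition")
})

test_that("the wild-type partition reproduces the anchor arithmetic", {
  comp <- photokin:::composition_from_anchors(wt74$a4, wt74$a5,
                                              b5 = 0.19, c5 = 0.10)
  p <- partition_two_cycle(comp)
  expect_equal(p$conductive_fraction, 0.51)
  expect_equal(unname(p$cycle2["R", 6]), 0.49)
  expect_equal(p$meta$shared_total_cycle1, 0.37)
  expect_equal(unname(p$shared["N2", 5] + p$shared["M", 5] +
                        p$shared["R_early", 5]), 1 - wt74$a5)
  three <- split_three_cycle(p)
  expect_equal(three$o1, 0.37)
  expect_equal(three$o2, 0.14)
  expect_equal(three$o1 + three$o2, p$conductive_fraction)
})

test_that("reassembling the partition restores the composition exactly", {
  for (cond in c("wt_ph74", "wt_ph55", "wt_ph85", "a75e_ph74",
                 "d234n_ph74", "d234n_ph45", "s97e_ph74")) {
    fr <- gtacr1_fractions(cond)
    comp <- photokin:::composition_from_anchors(fr$a4, fr$a5)
    p <- partition_two_cycle(comp)
    expect_equal(reassemble_partition(p), comp$fractions,
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("inconsistent compositions are rejected with tolerance", {
  comp <- photokin:::composition_from_anchors(0.51, 0.14)
  bad <- comp
  bad$fractions["K-like", 2] <- 0.40            # below the plateau level
  expect_error(partition_two_cycle(bad), "inconsistent composition")
  bad2 <- comp
  bad2$fractions["K-like", 5] <- 0.60           # In5 K above the plateau
  expect_error(partition_two_cycle(bad2), "exceeds the conductive fraction")
  # small (two-decimal rounding) violations pass
  near <- comp
  near$fractions["K-like", 2] <- 0.50
  expect_s3_class(partition_two_cycle(near), "cycle_partition")
})

test_that("shared-state allocations enumerate the full feasible lattice", {
  comp <- photokin:::composition_from_anchors(0.51, 0.14, b5 = 0.19,
                                              c5 = 0.10)
  p <- partition_two_cycle(comp)
  alloc <- enumerate_shared_allocations(p, grid_step = 0.01)
  need <- p$meta$shared_total_cycle1
  expect_true(all(abs(rowSums(alloc) - need) < 1e-6))
  expect_true(all(alloc$N2 <= 0.19 + 1e-9))
  expect_true(all(alloc$M <= 0.10 + 1e-9))
  expect_true(all(alloc$R_early <= 0.57 + 1e-9))
  # brute-force count over the same lattice
  brute <- 0L
  for (n2 in seq(0, 0.19, by = 0.01)) for (mm in seq(0, 0.10, by = 0.01)) {
    r <- need - n2 - mm
    if (r > -1e-9 && r < 0.57 + 1e-9 &&
        min(abs(seq(0, 0.57, by = 0.01) - r)) < 1e-6) brute <- brute + 1L
  }
  expect_equal(nrow(alloc), brute)
  # the all-to-one-cycle corner cases are present
  expect_true(any(abs(alloc$N2 - 0.19) < 1e-9 & abs(alloc$M - 0.10) < 1e-9 &
                    abs(alloc$R_early - 0.08) < 1e-9))
})

test_that("three-cycle split across all conditions matches the quoted values", {
  expected <- list(
    wt_ph55 = c(o1 = 0.29, o2 = 0.09),
    wt_ph85 = c(o1 = 0.42, o2 = 0.06),
    d234n_ph74 = c(o1 = 0.05, o2 = 0.06),
    d234n_ph45 = c(o1 = 0.07, o2 = 0.02),
    s97e_ph74 = c(o1 = 0.08, o2 = 0.03))
  for (cond in names(expected)) {
    fr <- gtacr1_fractions(cond)
    comp <- photokin:::composition_from_anchors(fr$a4, fr$a5)
    three <- split_three_cycle(partition_two_cycle(comp))
    expect_equal(three$o1, unname(expected[[cond]]["o1"]), tolerance = 1e-12)
    expect_equal(three$o2, unname(expected[[cond]]["o2"]), tolerance = 1e-12)
  }
})

test_that("the acidic S97E partition has no shared states and a silent K", {
  fr <- gtacr1_fractions("s97e_ph56")
  comp <- photokin:::composition_from_anchors(0.30, 0.03, a3 = 0.30)
  p <- partition_s97e_lowpH(comp, fr$alloc)
  expect_null(p$shared)
  expect_equal(p$conductive_fraction, 0.03)     # only Cycle1b conducts
  expect_equal(p$o1, 0)
  expect_false(p$meta$n1_prime_conductive)
  expect_identical(p$meta$n1_prime_form, "L'")
  # Cycle2's K persists unchanged through In3 -> In4
  expect_equal(unname(p$cycle2["K", 3]), unname(p$cycle2["K", 4]))
  expect_error(partition_s97e_lowpH(comp, c(cycle1a = 0.2, cycle1b = 0.2,
                                            cycle2 = 0.2)),
               "allocations sum")
})
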