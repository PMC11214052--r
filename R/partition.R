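#' Published composition fractions for GtACR1 conditions
#'
#' Conductive-cycle K-like fractions for each protein/pH condition, as used
#' to anchor the parallel-cycle partition: `a4` is the K-like content of
#' In4 (the conductive fraction, set by the photocurrent plateau) and `a5`
#' the K-like content of In5 (the slow conductive O2 state).  For the S97E
#' mutant at pH 5.6 the In3 K-like content splits between three cycles
#' (`cycle1a`, `cycle1b`, `cycle2`).
#'
#' @param condition one of `"wt_ph74"`, `"wt_ph55"`, `"wt_ph85"`,
#'   `"a75e_ph74"`, `"d234n_ph74"`, `"d234n_ph45"`, `"s97e_ph74"`,
#'   `"s97e_ph56"`; omit for the full table.
#' @return a list (or list of lists) of fraction values.
#' @export
gtacr1_fractions <- function(condition = NULL) {
  tab <- list(
    wt_ph74    = list(a4 = 0.51, a5 = 0.14),
    wt_ph55    = list(a4 = 0.38, a5 = 0.09),
    wt_ph85    = list(a4 = 0.48, a5 = 0.06),
    a75e_ph74  = list(a4 = 0.51, a5 = 0.38),
    d234n_ph74 = list(a4 = 0.11, a5 = 0.06),
    d234n_ph45 = list(a4 = 0.09, a5 = 0.02),
    s97e_ph74  = list(a4 = 0.11, a5 = 0.03),
    s97e_ph56  = list(k_in3 = 0.30,
                      alloc = c(cycle1a = 0.07, cycle1b = 0.03,
                                cycle2 = 0.20))
  )
  if (is.null(condition)) return(tab)
  if (!condition %in% names(tab)) {
    stop("unknown condition: ", condition)
  }
  tab[[condition]]
}

# build a minimal, mass-consistent 4x6 composition matrix from the
# anchoring fractions; used for worked examples and tests
composition_from_anchors <- function(a4, a5, a2 = NULL, a3 = NULL,
                                     b5 = NULL, c5 = 0) {
  noncond <- 1 - a4
  if (is.null(a2)) a2 <- a4 + noncond / 2
  if (is.null(a3)) a3 <- a4 + noncond / 3
  if (is.null(b5)) b5 <- min(0.19, 1 - a5 - c5)
  d5 <- 1 - a5 - b5 - c5
  M <- rbind(
    "K-like" = c(1, a2, a3, a4, a5, 0),
    "L-like" = c(0, 1 - a2, 1 - a3, 1 - a4, b5, 0),
    "M"      = c(0, 0, 0, 0, c5, 0),
    "R"      = c(0, 0, 0, 0, d5, 1))
  colnames(M) <- sprintf("In%d", 1:6)
  composition_matrix(M)
}

#' Partition a composition matrix into conductive and nonconductive cycles
#'
#' Implements the two-cycle partition: the photocurrent plateau fixes the
#' K-like fraction `a4` belonging to the conductive Cycle1 (K state through
#' In1--In3, the open O state in In4 and In5, recovering to R).  The
#' remaining K-like fraction `1 - a4`, the L-like content (L1 + L2
#' equilibria, then N1) and any early M belong to the nonconductive Cycle2,
#' which recovers `1 - a4` of R.  The L-like, M and R content of In5 cannot
#' be assigned from the data alone; these are the shared states (N2, M,
#' early-recovered R), totalling `a4 - a5` on the Cycle1 side.
#'
#' @param comp a [composition_matrix()] with rows K-like, L-like, M, R and
#'   columns In1..In6.
#' @param conductive_a4 optional override of the conductive fraction; by
#'   default the K-like In4 entry (the current plateau level).
#' @param tol tolerance for negative derived fractions (default 0.02,
#'   matching two-decimal reporting of composition data).
#' @return object of class `"cycle_partition"` with elements `cycle1`,
#'   `cycle2`, `shared` (per-In fraction tables), `conductive_fraction`,
#'   `a5`, `comp`, and `meta` (notes, including the convention that Cycle2
#'   recovers `1 - a4` of R).
#' @export
partition_two_cycle <- function(comp, conductive_a4 = NULL, tol = 0.02) {
  stopifnot(inherits(comp, "composition_matrix"))
  M <- comp$fractions
  stopifnot(all(c("K-like", "L-like", "M", "R") %in% rownames(M)),
            ncol(M) == 6)
  a <- M["K-like", ]; b <- M["L-like", ]; cM <- M["M", ]; d <- M["R", ]
  a4 <- if (is.null(conductive_a4)) unname(a[4]) else conductive_a4
  a5 <- unname(a[5])
  if (a4 - a[2] > tol || a4 - a[3] > tol) {
    stop(sprintf(
      "inconsistent composition: conductive fraction %.3f exceeds K-like In2/In3 (%.3f, %.3f)",
      a4, a[2], a[3]))
  }
  if (a5 - a4 > tol) stop("K-like In5 exceeds the conductive fraction")
  ins <- colnames(M)
  z <- setNames(rep(0, 6), ins)
  cycle1 <- rbind(
    K = replace(z, 1:3, a4),
    O = replace(z, 4:5, c(a4, a5)),
    R = replace(z, 6, a4))
  cycle2 <- rbind(
    K       = replace(z, 1:3, pmax(c(1 - a4, a[2] - a4, a[3] - a4), 0)),
    `L1+L2` = replace(z, 2:3, b[2:3]),
    N1      = replace(z, 4, b[4]),
    M1      = replace(z, 4, cM[4]),
    R       = replace(z, 6, 1 - a4))
  shared <- rbind(
    N2      = replace(z, 5, b[5]),
    M       = replace(z, 5, cM[5]),
    R_early = replace(z, 5, d[5]))
  structure(
    list(cycle1 = cycle1, cycle2 = cycle2, shared = shared,
         conductive_fraction = a4, a5 = a5, comp = comp,
         meta = list(
           note = paste(
             "Cycle2 final R rendered as the nonconductive fraction",
             "(1 - a4); the tabulated form lists a4 for both cycles,",
             "the text assigns 1 - a4 to Cycle2."),
           shared_total_cycle1 = a4 - a5)),
    class = "cycle_partition")
}

#' @export
print.cycle_partition <- function(x, ...) {
  cat(sprintf("<cycle_partition> conductive %.2f / nonconductive %.2f\n",
              x$conductive_fraction, 1 - x$conductive_fraction))
  cat("Cycle1:\n"); print(round(x$cycle1, 3))
  cat("Cycle2:\n"); print(round(x$cycle2, 3))
  cat("Shared (In5):\n"); print(round(x$shared, 3))
  invisible(x)
}

#' Split the conductive cycle into two parallel conductive cycles
#'
#' The fast- and slow-decaying conductive states O1 and O2 may belong to
#' separate cycles: Cycle1a keeps `O1 = a4 - a5` (reduced by the O2 amount)
#' and Cycle1b is the uniquely defined chain `K -> O2 -> R` with
#' `O2 = a5`; the K -> O2 rate is taken equal to the K -> O1 rate.
#'
#' @param partition a [partition_two_cycle()] result.
#' @return object of class `"three_cycle_partition"` with `o1`, `o2`,
#'   `cycle1a`, `cycle1b`, `cycle2`, `shared`, `conductive_fraction`.
#' @export
split_three_cycle <- function(partition) {
  stopifnot(inherits(partition, "cycle_partition"))
  a4 <- partition$conductive_fraction
  a5 <- partition$a5
  if (a5 > a4 + 1e-12) stop("O2 fraction (a5) exceeds the conductive fraction (a4)")
  o1 <- a4 - a5
  ins <- colnames(partition$cycle1)
  z <- setNames(rep(0, length(ins)), ins)
  cycle1a <- rbind(
    K  = replace(z, 1:3, o1),
    O1 = replace(z, 4, o1),
    R  = replace(z, 6, o1))
  cycle1b <- rbind(
    K  = replace(z, 1:3, a5),
    O2 = replace(z, 4:5, a5),
    R  = replace(z, 6, a5))
  structure(
    list(o1 = o1, o2 = a5, cycle1a = cycle1a, cycle1b = cycle1b,
         cycle2 = partition$cycle2, shared = partition$shared,
         conductive_fraction = a4,
         meta = c(partition$meta,
                  list(note_1b = "Cycle1b shares no intermediates; K->O2 rate set equal to K->O1"))),
    class = "three_cycle_partition")
}

#' @export
print.three_cycle_partition <- function(x, ...) {
  cat(sprintf(
    "<three_cycle_partition> O1 = %.2f (Cycle1a), O2 = %.2f (Cycle1b), conductive %.2f\n",
    x$o1, x$o2, x$conductive_fraction))
  invisible(x)
}

#' Three-cycle partition for the S97E variant at acidic pH
#'
#' At low pH the usual conductive O1 state is absent: the K-like In3
#' content splits between a nonconductive Cycle1a (K -> N'1 -> N2 -> R,
#' with N'1 carrying an L'-like spectrum and a conductive flag of FALSE),
#' the conductive Cycle1b (K -> O2 -> R) and Cycle2, whose K stays
#' spectrally silent through the In3 -> In4 transition.  Unlike the silent
#' K -> O step of the other conditions, K -> N'1 is spectrally visible.
#'
#' @param comp a [composition_matrix()].
#' @param allocations named fractions `cycle1a`, `cycle1b`, `cycle2`
#'   summing to the K-like In3 entry (within 0.01).
#' @return object of class `"three_cycle_partition"` with additional
#'   elements `variant = "s97e_lowpH"`, `allocations`, and state metadata
#'   (`n1_prime_form = "L'"`, `n1_prime_conductive = FALSE`).
#' @export
partition_s97e_lowpH <- function(comp, allocations) {
  stopifnot(inherits(comp, "composition_matrix"),
            all(c("cycle1a", "cycle1b", "cycle2") %in% names(allocations)))
  k3 <- comp$fractions["K-like", 3]
  if (abs(sum(allocations) - k3) > 0.01) {
    stop(sprintf(
      "allocations sum to %.3f but K-like In3 is %.3f (tolerance 0.01)",
      sum(allocations), k3))
  }
  ins <- colnames(comp$fractions)
  z <- setNames(rep(0, length(ins)), ins)
  f1a <- unname(allocations[["cycle1a"]])
  f1b <- unname(allocations[["cycle1b"]])
  f2 <- unname(allocations[["cycle2"]])
  cycle1a <- rbind(
    K       = replace(z, 1:3, f1a),
    `N'1`   = replace(z, 4, f1a),
    N2      = replace(z, 5, f1a),
    R       = replace(z, 6, f1a))
  cycle1b <- rbind(
    K  = replace(z, 1:3, f1b),
    O2 = replace(z, 4:5, f1b),
    R  = replace(z, 6, f1b))
  cycle2 <- rbind(
    K        = replace(z, 1:4, f2),   # silent through In3 -> In4
    `L'1+L'2` = replace(z, 2:4, comp$fractions["L-like", 2:4]),
    N2       = replace(z, 5, comp$fractions["L-like", 5]),
    R        = replace(z, 6, 1 - f1a - f1b))
  structure(
    list(o1 = 0, o2 = f1b, cycle1a = cycle1a, cycle1b = cycle1b,
         cycle2 = cycle2,
         shared = NULL,   # no shared states at low pH
         conductive_fraction = f1b,
         variant = "s97e_lowpH", allocations = allocations,
         meta = list(n1_prime_form = "L'", n1_prime_conductive = FALSE,
                     note = "nonconductive N'1 replaces the conductive O1")),
    class = "three_cycle_partition")
}

#' Enumerate allocations of the shared states between the cycles
#'
#' The N2, M and early-recovered R content of In5 can complement the
#' conductive cycle in any combination totalling its fast-decay mass
#' (`a4 - a5`); the remainder goes to Cycle2.  This enumerates all
#' grid-feasible splits.
#'
#' @param partition a [partition_two_cycle()] result.
#' @param grid_step allocation grid step (fraction units, > 0).
#' @return data frame with columns `N2`, `M`, `R_early` (amounts assigned
#'   to Cycle1; Cycle2 receives the complement), one row per feasible
#'   allocation.  Zero shared mass yields the single empty allocation.
#' @export
enumerate_shared_allocations <- function(partition, grid_step = 0.01) {
  stopifnot(inherits(partition, "cycle_partition"), grid_step > 0)
  totals <- c(N2 = unname(partition$shared["N2", 5]),
              M = unname(partition$shared["M", 5]),
              R_early = unname(partition$shared["R_early", 5]))
  need <- partition$meta$shared_total_cycle1
  eps <- grid_step * 1e-6
  if (sum(totals) < need - eps) {
    stop("shared mass insufficient to complement the conductive cycle")
  }
  if (need <= eps && sum(totals) <= eps) {
    return(data.frame(N2 = 0, M = 0, R_early = 0))
  }
  grid_vals <- function(tot) seq(0, tot, by = grid_step)
  g <- expand.grid(N2 = grid_vals(totals["N2"]),
                   M = grid_vals(totals["M"]),
                   R_early = grid_vals(totals["R_early"]))
  keep <- abs(rowSums(g) - need) < eps + 1e-9
  out <- g[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reassemble a partition into a composition matrix (mass-balance check)
#'
#' @param partition a [partition_two_cycle()] result.
#' @return 4 x 6 matrix in the layout of the input composition.
#' @export
reassemble_partition <- function(partition) {
  stopifnot(inherits(partition, "cycle_partition"))
  c1 <- partition$cycle1; c2 <- partition$cycle2; sh <- partition$shared
  rbind(
    "K-like" = c1["K", ] + c1["O", ] + c2["K", ],
    "L-like" = c2["L1+L2", ] + c2["N1", ] + sh["N2", ],
    "M"      = c2["M1", ] + sh["M", ],
    "R"      = c1["R", ] + c2["R", ] + sh["R_early", ])
}
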