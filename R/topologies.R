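# ---- scheme topology templates -------------------------------------------
#
# Naming: k_open is the spectrally silent channel-opening rate (fixed by
# convention from the current rise, never fitted from spectra); k_slow is
# the shared late-ms recovery rate (all slow recovery branches use the same
# slot, enforcing O2->R = N2->R = M->R); branch slots from O1/N1 carry the
# early-ms apparent rate split by product fractions.

tr_df <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(from = m[, 1], to = m[, 2], slot = m[, 3])
}

map_c1 <- c(K = "K-like", O = "K-like", O1 = "K-like", O2 = "K-like",
            N2 = "L-like", M = "M", R = "R")
map_c2 <- c(K = "K-like", L1 = "L-like", L2 = "L-like", N1 = "L-like",
            N2 = "L-like", M1 = "M", M = "M", R = "R")

topo_cycle1_branching <- function(initial = c(K = 0.51), with_M = TRUE,
                                  with_O1R = TRUE) {
  tr <- tr_df("K", "O1", "k_open",
              "O1", "O2", "k_o1_o2",
              "O1", "N2", "k_o1_n2",
              "O2", "R", "k_slow",
              "N2", "R", "k_slow")
  if (with_M) tr <- rbind(tr, tr_df("O1", "M", "k_o1_m", "M", "R", "k_slow"))
  if (with_O1R) tr <- rbind(tr, tr_df("O1", "R", "k_o1_r"))
  states <- unique(c(tr$from, tr$to))
  scheme_topology("cycle1_branching_general", states, tr,
                  mapping = map_c1[states], initial = initial,
                  fixed = c(k_open = NA_real_),
                  conductive = c("O1", "O2"), class = "branching")
}

topo_cycle1_equilibrium <- function(initial = c(K = 0.51)) {
  tr <- tr_df("K", "O", "k_open",
              "O", "R", "k_o_r",
              "O", "N2", "k_o_n2",
              "N2", "O", "k_n2_o")
  scheme_topology("cycle1_equilibrium_ON2", c("K", "O", "N2", "R"), tr,
                  mapping = map_c1[c("K", "O", "N2", "R")], initial = initial,
                  fixed = c(k_open = NA_real_),
                  conductive = "O", class = "equilibrium")
}

topo_cycle1a <- function(initial = c(K = 0.37), with_M = TRUE,
                         with_O1R = TRUE) {
  tr <- tr_df("K", "O1", "k_open",
              "O1", "N2", "k_o1_n2",
              "N2", "R", "k_slow")
  if (with_M) tr <- rbind(tr, tr_df("O1", "M", "k_o1_m", "M", "R", "k_slow"))
  if (with_O1R) tr <- rbind(tr, tr_df("O1", "R", "k_o1_r"))
  states <- unique(c(tr$from, tr$to))
  scheme_topology("cycle1a_general", states, tr,
                  mapping = map_c1[states], initial = initial,
                  fixed = c(k_open = NA_real_),
                  conductive = "O1", class = "branching")
}

topo_cycle1b <- function(initial = c(K = 0.14)) {
  scheme_topology("cycle1b_chain", c("K", "O2", "R"),
                  tr_df("K", "O2", "k_open", "O2", "R", "k_slow"),
                  mapping = map_c1[c("K", "O2", "R")], initial = initial,
                  fixed = c(k_open = NA_real_),
                  conductive = "O2", class = "branching")
}

topo_cycle2_branching <- function(initial = c(K = 0.49), with_M = TRUE,
                                  with_N1R = TRUE, early_M1 = FALSE) {
  tr <- tr_df("K", "L1", "k_kl1",
              "L1", "K", "k_l1k",
              "K", "L2", "k_kl2",
              "L2", "K", "k_l2k",
              "L2", "N1", "k_l2n1",
              "N1", "N2", "k_n1_n2",
              "N2", "R", "k_slow")
  if (with_M) tr <- rbind(tr, tr_df("N1", "M", "k_n1_m", "M", "R", "k_slow"))
  if (with_N1R) tr <- rbind(tr, tr_df("N1", "R", "k_n1_r"))
  if (early_M1) tr <- rbind(tr, tr_df("L2", "M1", "k_l2m1", "M1", "M", "k_m1_m"))
  states <- unique(c(tr$from, tr$to))
  nm <- if (early_M1) "cycle2_earlyM1" else "cycle2_branching_general"
  scheme_topology(nm, states, tr, mapping = map_c2[states],
                  initial = initial, class = "branching")
}

topo_cycle2_equilibrium <- function(initial = c(K = 0.49)) {
  tr <- tr_df("K", "L1", "k_kl1",
              "L1", "K", "k_l1k",
              "K", "L2", "k_kl2",
              "L2", "K", "k_l2k",
              "L2", "N1", "k_l2n1",
              "N1", "N2", "k_n1_n2",
              "N2", "N1", "k_n2_n1",
              "N1", "R", "k_n1_r")
  states <- unique(c(tr$from, tr$to))
  scheme_topology("cycle2_equilibrium", states, tr,
                  mapping = map_c2[states], initial = initial,
                  class = "equilibrium")
}

topo_s97e_triple <- function(alloc = c(cycle1a = 0.07, cycle1b = 0.03,
                                       cycle2 = 0.20)) {
  tr <- tr_df(
    # Cycle1a: nonconductive N'1 replaces the usual conductive O1
    "Ka", "N1p", "k_k_n1p",
    "N1p", "N2a", "k_n1p_n2",
    "N2a", "Ra", "k_slow",
    # Cycle1b: the simple conductive chain
    "Kb", "O2", "k_open",
    "O2", "Rb", "k_slow",
    # Cycle2: early L' equilibria, K silent through In3 -> In4
    "Kc", "Lp1", "k_kl1",
    "Lp1", "Kc", "k_l1k",
    "Kc", "Lp2", "k_kl2",
    "Lp2", "Kc", "k_l2k",
    "Lp2", "N2c", "k_l2_n2",
    "N2c", "Rc", "k_slow")
  states <- unique(c(tr$from, tr$to))
  mapping <- c(Ka = "K-like", N1p = "L'", N2a = "L-like", Ra = "R",
               Kb = "K-like", O2 = "K-like", Rb = "R",
               Kc = "K-like", Lp1 = "L'", Lp2 = "L'", N2c = "L-like",
               Rc = "R")
  scheme_topology("s97e_lowpH_triple", states, tr, mapping = mapping[states],
                  initial = c(Ka = unname(alloc[["cycle1a"]]),
                              Kb = unname(alloc[["cycle1b"]]),
                              Kc = unname(alloc[["cycle2"]])),
                  fixed = c(k_open = NA_real_),
                  conductive = "O2", class = "branching")
}

#' Catalog of scheme topologies per protein/pH condition
#'
#' Returns the applicable equilibrium and branching templates, pruned per
#' condition: the wild type at pH 5.5 lacks the M state; A75E lacks the fast
#' O1 -> R recovery and the N1 -> R branch but adds an early M1 branch from
#' L2; D234N lacks the O1 -> R and N1 -> R branches (with the extra
#' M1 branch at pH 7.4); S97E at pH 5.6 is the three-cycle variant with no
#' shared states.
#'
#' @param protein_condition one of `"wt_ph55"`, `"wt_ph74"`, `"wt_ph85"`,
#'   `"a75e_ph74"`, `"d234n_ph74"`, `"d234n_ph45"`, `"s97e_ph74"`,
#'   `"s97e_ph56"`, or `"generic"`.  Unknown labels fall back to the generic
#'   catalog with a warning.
#' @return named list of [scheme_topology()] objects.
#' @export
topology_catalog <- function(protein_condition = "generic") {
  known <- c("generic", "wt_ph55", "wt_ph74", "wt_ph85", "a75e_ph74",
             "d234n_ph74", "d234n_ph45", "s97e_ph74", "s97e_ph56")
  if (!protein_condition %in% known) {
    warning("unknown condition '", protein_condition,
            "': returning the generic catalog")
    protein_condition <- "generic"
  }
  fr <- tryCatch(gtacr1_fractions(protein_condition), error = function(e)
    list(a4 = 0.51, a5 = 0.14))
  if (protein_condition == "s97e_ph56") {
    return(list(s97e_lowpH_triple = topo_s97e_triple(fr$alloc)))
  }
  a4 <- fr$a4; a5 <- fr$a5
  with_M <- protein_condition != "wt_ph55"
  with_O1R <- !protein_condition %in% c("a75e_ph74", "d234n_ph74",
                                        "d234n_ph45")
  with_N1R <- with_O1R
  early_M1 <- protein_condition %in% c("a75e_ph74", "d234n_ph74")
  cat_list <- list(
    cycle1_branching_general =
      topo_cycle1_branching(c(K = a4), with_M, with_O1R),
    cycle1a_general = topo_cycle1a(c(K = a4 - a5), with_M, with_O1R),
    cycle1b_chain = topo_cycle1b(c(K = a5)),
    cycle2_branching_general =
      topo_cycle2_branching(c(K = 1 - a4), with_M, with_N1R, early_M1),
    cycle1_equilibrium_ON2 = topo_cycle1_equilibrium(c(K = a4)),
    cycle2_equilibrium = topo_cycle2_equilibrium(c(K = 1 - a4)))
  cat_list
}

#' Compare equilibrium and branching scheme fits
#'
#' Equilibrium and branching patterns are kinetically equivalent: both
#' classes reproduce the apparent rates and b-spectra equally well, so the
#' choice between them cannot be made statistically.  This report records
#' that equivalence and tags equilibrium schemes as mechanistically
#' rejected: repeated opening/closing of the channel within one reaction
#' chain, and dark equilibria between open and closed states, are
#' physically unrealistic for a light-gated channel.  A bookkeeping
#' classification, not a statistical test.
#'
#' @param fit_results list of [fit_scheme_rates()] results (>= 1 per class
#'   for a full comparison).
#' @return object of class `"scheme_class_report"`: per-class best
#'   objectives, `equivalent` (within a factor of 2), `verdict`, `note`.
#' @export
classify_equilibrium_vs_branching <- function(fit_results) {
  if (length(fit_results) == 0) stop("no fit results supplied")
  cls <- vapply(fit_results, function(f) f$topology$pattern_class, "")
  objs <- vapply(fit_results, function(f) f$objective, 0)
  best <- tapply(objs, cls, min)
  if (length(best) < 2) {
    return(structure(list(
      best_objectives = as.list(best), equivalent = NA,
      verdict = NA_character_,
      note = sprintf("only the %s class supplied: comparison missing",
                     names(best))),
      class = "scheme_class_report"))
  }
  floor_obj <- pmax(best, .Machine$double.eps)
  equivalent <- max(floor_obj) / min(floor_obj) < 2 ||
    max(best) < 1e-10
  structure(list(
    best_objectives = as.list(best),
    equivalent = equivalent,
    verdict = "equilibrium schemes mechanistically rejected",
    note = paste("both pattern classes describe the kinetic data;",
                 "equilibrium between conductive and nonconductive states",
                 "in one chain is rejected on physical grounds")),
    class = "scheme_class_report")
}

#' @export
print.scheme_class_report <- function(x, ...) {
  cat("<scheme_class_report>\n")
  for (nm in names(x$best_objectives)) {
    cat(sprintf("  best %s objective: %.4g\n", nm, x$best_objectives[[nm]]))
  }
  if (!is.na(x$equivalent)) {
    cat("  kinetically equivalent:", x$equivalent, "\n  verdict:", x$verdict, "\n")
  } else {
    cat(" ", x$note, "\n")
  }
  invisible(x)
}
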