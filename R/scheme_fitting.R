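#' Kinetic scheme topology with free and fixed rate slots
#'
#' A template for [fit_scheme_rates()]: states, transitions labelled by rate
#' slot, slots fixed by convention (e.g. the spectrally silent channel
#' opening rate, taken from the current rise), and equality constraints
#' (e.g. all slow recovery branches sharing the late-ms apparent rate).
#'
#' @param name topology identifier.
#' @param states state labels.
#' @param transitions data frame with columns `from`, `to`, `slot`.
#' @param mapping named character state -> spectral form.
#' @param initial named initial populations.
#' @param fixed named numeric of fixed slot rates (may be `NA` to mark a
#'   slot as fixed-by-input, to be supplied at fit time).
#' @param constraints list of character vectors; slots in one vector share a
#'   single rate.
#' @param conductive conductive state labels.
#' @param class `"branching"` or `"equilibrium"` (scheme pattern class).
#' @return object of class `"scheme_topology"`.
#' @export
scheme_topology <- function(name, states, transitions, mapping, initial,
                            fixed = numeric(0), constraints = list(),
                            conductive = character(0),
                            class = c("branching", "equilibrium")) {
  class <- match.arg(class)
  stopifnot(all(c("from", "to", "slot") %in% names(transitions)))
  slots <- unique(transitions$slot)
  stopifnot(all(names(fixed) %in% slots),
            all(unlist(constraints) %in% slots))
  structure(
    list(name = name, states = states, transitions = transitions,
         mapping = mapping, initial = initial, fixed = fixed,
         constraints = constraints, conductive = conductive,
         pattern_class = class),
    class = "scheme_topology")
}

#' @export
print.scheme_topology <- function(x, ...) {
  cat(sprintf("<scheme_topology> %s (%s): %d states, free slots: %s\n",
              x$name, x$pattern_class, length(x$states),
              paste(free_slots(x), collapse = ", ")))
  invisible(x)
}

# map every slot to its constraint-group representative
slot_representative <- function(topology) {
  slots <- unique(topology$transitions$slot)
  rep_of <- setNames(slots, slots)
  for (grp in topology$constraints) rep_of[grp] <- grp[1]
  rep_of
}

#' Free rate slots of a topology
#'
#' One representative per equality-constraint group, excluding fixed slots.
#'
#' @param topology a [scheme_topology()].
#' @return character vector of slot names.
#' @export
free_slots <- function(topology) {
  rep_of <- slot_representative(topology)
  setdiff(unique(rep_of), names(topology$fixed))
}

#' Instantiate a topology with concrete rates
#'
#' @param topology a [scheme_topology()].
#' @param rates named rates for the free slots (and any fixed slot left `NA`
#'   in the template).
#' @param initial optional override of the initial populations.
#' @return a [kinetic_scheme()].
#' @export
instantiate_topology <- function(topology, rates, initial = NULL) {
  rep_of <- slot_representative(topology)
  vals <- topology$fixed
  vals[names(rates)] <- rates
  missing <- setdiff(unique(rep_of), names(vals))
  if (length(missing)) {
    stop("no rate for slot(s): ", paste(missing, collapse = ", "))
  }
  tr <- topology$transitions
  tr$rate <- as.numeric(vals[rep_of[tr$slot]])
  if (anyNA(tr$rate)) stop("fixed-by-input slot(s) left unset")
  kinetic_scheme(topology$states, tr[, c("from", "to", "rate")],
                 conductive = topology$conductive,
                 initial = if (is.null(initial)) topology$initial else initial)
}

#' Attach eigenvalue labels to fitted b-spectra
#'
#' Converts an [global_exp_fit()] result into a b-spectra matrix labelled by
#' eigenvalues (columns fastest first, the non-decaying spectrum labelled 0),
#' the form expected by [cycle2_target_b()] and [fit_scheme_rates()].
#'
#' @param kinetics an [global_exp_fit()] result.
#' @return matrix with attribute `"eigenvalues"`.
#' @export
b_matrix <- function(kinetics) {
  stopifnot(inherits(kinetics, "apparent_kinetics"))
  bs <- kinetics$b_spectra
  attr(bs, "eigenvalues") <- c(-1 / kinetics$lifetimes, 0)
  bs
}

#' Residual b-spectra targets for the nonconductive cycle
#'
#' With the conductive Cycle1 scheme fixed, the b-spectra left for Cycle2 to
#' reproduce are the total fitted b-spectra minus the Cycle1 contribution:
#' `bsf = bs - E x W_cy1`, combined by degeneracy group and matched to the
#' total spectra through their eigenvalues.
#'
#' @param bs_total b-spectra matrix with attribute `"eigenvalues"`
#'   (see [b_matrix()]).
#' @param cycle1_solution [eigen_solve()] result for the fixed Cycle1 scheme.
#' @param basis spectral basis.
#' @param mapping state -> form mapping covering the Cycle1 states.
#' @param match_tol relative eigenvalue tolerance for matching Cycle1
#'   components to total components (default 0.05).
#' @return matrix like `bs_total` with the Cycle1 contribution removed.
#'   Cycle1 eigencomponents with non-negligible spectra but no matching
#'   total component raise a degeneracy-group mismatch error.
#' @export
cycle2_target_b <- function(bs_total, cycle1_solution, basis, mapping,
                            match_tol = 0.05) {
  ev_tot <- attr(bs_total, "eigenvalues")
  if (is.null(ev_tot)) stop("bs_total must carry an 'eigenvalues' attribute")
  if (length(cycle1_solution$states) == 0) return(bs_total)
  bs1 <- compute_b_spectra(basis, cycle1_solution, mapping)
  ev1 <- attr(bs1, "eigenvalues")
  out <- bs_total
  data_norm <- sqrt(sum(bs_total^2))
  for (j in seq_along(ev1)) {
    comp_norm <- sqrt(sum(bs1[, j]^2))
    if (ev1[j] == 0) {
      k <- which(ev_tot == 0)
    } else {
      rel <- abs(ev_tot - ev1[j]) / abs(ev1[j])
      k <- which(rel < match_tol)
    }
    if (length(k) == 0) {
      if (comp_norm < 1e-9 * data_norm) next   # spectrally silent component
      stop(sprintf(
        "degeneracy-group mismatch: Cycle1 eigenvalue %.4g has no matching target rate",
        ev1[j]))
    }
    out[, k[1]] <- out[, k[1]] - bs1[, j]
  }
  attr(out, "eigenvalues") <- ev_tot
  out
}

# greedy nearest matching of achieved eigenvalue groups to target rates
match_eigen <- function(achieved, targets) {
  used <- logical(length(achieved))
  idx <- integer(length(targets))
  for (j in order(-abs(targets))) {
    d <- abs(log(pmax(abs(achieved), 1e-300)) - log(abs(targets[j])))
    d[used] <- Inf
    idx[j] <- which.min(d)
    used[idx[j]] <- TRUE
  }
  idx
}

#' Fit microscopic rates of a scheme topology
#'
#' Adjusts the free rates so the eigen-solution of the kinetic matrix
#' reproduces the target apparent rates (through its eigenvalues) and the
#' target b-spectra (through `E x W`, degenerate groups combined).  Rates
#' are optimized in log space (positivity built in) from multiple
#' deterministic starts; the objective is a weighted sum of squared relative
#' eigenvalue errors and the relative b-spectra residual.
#'
#' @param topology a [scheme_topology()].
#' @param target_rates apparent rates to reproduce (s^-1, positive).
#' @param target_b optional b-spectra matrix with attribute `"eigenvalues"`
#'   (see [b_matrix()], [cycle2_target_b()]).
#' @param basis spectral basis (required with `target_b`).
#' @param initial optional initial-population override.
#' @param fixed_rates named rates for fixed-by-input slots (template `NA`s).
#' @param n_starts number of log-uniform multi-starts (default 16).
#' @param seed deterministic seed for the starts.
#' @param weights two weights, `rate` and `b` (default both 1; they balance
#'   the terms so each contributes comparably at equal relative error).
#' @param rate_tol relative eigenvalue tolerance for declaring success
#'   (default 0.005).
#' @param start_center optional named starting rates used as the first
#'   (heuristic) start.
#' @param accept optional predicate on the named free-rate vector; candidate
#'   optima violating it are discarded.  Used to impose labeling conventions
#'   that resolve exchange symmetries between isospectral states (two states
#'   of the same spectral form can swap roles without changing the data, so
#'   a convention such as "L1 is the faster equilibrium" is required for the
#'   rates to be well defined).
#' @return object of class `"fit_result"`: `rates` (all slots), `free`
#'   (fitted free slots), `eigenvalues`, `b_spectra`, `objective`,
#'   `rate_errors` (relative, per target), `b_residual` (relative),
#'   `converged`, `success`, `identifiability` (flat-direction report),
#'   `scheme`, `topology`.
#' @export
fit_scheme_rates <- function(topology, target_rates, target_b = NULL,
                             basis = NULL, initial = NULL,
                             fixed_rates = numeric(0),
                             n_starts = 16, seed = 1,
                             weights = c(rate = 1, b = 1),
                             rate_tol = 0.005, start_center = NULL,
                             accept = NULL) {
  stopifnot(inherits(topology, "scheme_topology"),
            all(is.finite(target_rates)), all(target_rates > 0))
  if (!is.null(target_b) && is.null(basis)) {
    stop("`basis` is required when fitting b-spectra targets")
  }
  topo <- topology
  if (length(fixed_rates)) topo$fixed[names(fixed_rates)] <- fixed_rates
  fs <- free_slots(topo)
  if (length(fs) == 0) stop("topology has no free slots to fit")
  ev_tgt <- if (!is.null(target_b)) attr(target_b, "eigenvalues") else NULL
  b_norm2 <- if (!is.null(target_b)) sum(target_b^2) else 1

  evaluate <- function(logr, detail = FALSE) {
    rates <- setNames(exp(logr), fs)
    sol <- tryCatch(
      suppressWarnings(eigen_solve(build_kinetic_matrix(
        instantiate_topology(topo, rates, initial)))),
      error = function(e) NULL)
    if (is.null(sol)) {
      if (detail) return(NULL)
      return(1e6)
    }
    groups <- sol$degeneracy_groups
    grp_ev <- vapply(groups, function(g) sol$eigenvalues[g[1]], 0)
    nz <- grp_ev != 0
    idx <- match_eigen(grp_ev[nz], -target_rates)
    ach <- grp_ev[nz][idx]
    rate_err <- (abs(ach) - target_rates) / target_rates
    obj <- weights[["rate"]] * sum(rate_err^2)
    b_res <- NA_real_
    bs <- NULL
    if (!is.null(target_b)) {
      bs <- compute_b_spectra(basis, sol, topo$mapping)
      ev_ach <- attr(bs, "eigenvalues")
      resid2 <- 0
      for (j in seq_along(ev_tgt)) {
        if (ev_tgt[j] == 0) {
          k <- which(ev_ach == 0)
        } else {
          k <- which.min(abs(log(pmax(abs(ev_ach), 1e-300)) -
                             log(abs(ev_tgt[j]))))
        }
        bj <- if (length(k)) bs[, k[1]] else 0
        resid2 <- resid2 + sum((target_b[, j] - bj)^2)
      }
      b_res <- sqrt(resid2 / b_norm2)
      obj <- obj + weights[["b"]] * resid2 / b_norm2
    }
    if (!detail) return(obj)
    list(obj = obj, rates = rates, sol = sol, rate_err = rate_err,
         b_res = b_res, bs = bs)
  }

  lo <- log(min(target_rates) / 30)
  hi <- log(max(target_rates) * 30)
  starts <- with_seed(seed, {
    s <- lapply(seq_len(n_starts), function(i) runif(length(fs), lo, hi))
    if (!is.null(start_center)) {
      s[[1]] <- log(start_center[fs])
      if (n_starts > 1) {
        s[[2]] <- log(start_center[fs]) + rnorm(length(fs), sd = 0.3)
      }
    }
    s
  })
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, evaluate, method = "Nelder-Mead",
            control = list(maxit = 4000, reltol = 1e-13)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (!is.null(accept) && !isTRUE(accept(setNames(exp(fit$par), fs)))) next
    better <- is.null(best) || fit$value < best$value * (1 - 1e-9)
    tie <- !is.null(best) && abs(fit$value - best$value) <=
      1e-9 * max(abs(best$value), 1e-300)
    if (better || (tie && sum(exp(fit$par)^2) < sum(exp(best$par)^2))) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop("all optimization starts failed",
         if (!is.null(accept)) " or violated the labeling convention")
  }
  det <- evaluate(best$par, detail = TRUE)
  # flat-direction (identifiability) check via the objective's curvature
  h <- 1e-4
  n <- length(best$par)
  H <- matrix(0, n, n)
  f0 <- best$value
  for (i in seq_len(n)) for (j in i:n) {
    ei <- ej <- rep(0, n); ei[i] <- h; ej[j] <- h
    H[i, j] <- H[j, i] <-
      (evaluate(best$par + ei + ej) - evaluate(best$par + ei) -
         evaluate(best$par + ej) + f0) / h^2
  }
  he <- eigen(H, symmetric = TRUE)
  flat <- which(abs(he$values) < 1e-8 * max(abs(he$values), 1e-300))
  ident <- list(
    identifiable = length(flat) == 0,
    null_directions = if (length(flat)) {
      nd <- he$vectors[, flat, drop = FALSE]
      rownames(nd) <- fs
      nd
    } else NULL)
  success <- all(abs(det$rate_err) < rate_tol)
  all_rates <- topo$fixed
  all_rates[fs] <- det$rates
  structure(
    list(rates = all_rates, free = det$rates,
         eigenvalues = det$sol$eigenvalues, b_spectra = det$bs,
         objective = det$obj, rate_errors = det$rate_err,
         b_residual = det$b_res, converged = best$convergence == 0,
         success = success, identifiability = ident,
         scheme = instantiate_topology(topo, det$rates, initial),
         topology = topo),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s: objective %.4g, %s\n", x$topology$name,
              x$objective,
              if (x$success) "target rates reproduced" else "FAILED"))
  cat("  fitted rates (s^-1):\n")
  for (nm in names(x$free)) cat(sprintf("    %-12s %.5g\n", nm, x$free[[nm]]))
  cat(sprintf("  max |relative rate error| %.3g; b residual %.3g\n",
              max(abs(x$rate_errors)), x$b_residual))
  if (!x$identifiability$identifiable) {
    cat("  WARNING: flat objective direction(s) - not all rates identifiable\n")
  }
  invisible(x)
}

#' Export a fit result as JSON plus a CSV of achieved vs target rates
#'
#' @param fit a [fit_scheme_rates()] result.
#' @param path base path (`.json` and `.csv` are appended).
#' @param target_rates the rates the fit targeted.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path, target_rates) {
  jsonlite::write_json(
    list(topology = fit$topology$name, rates = as.list(fit$rates),
         objective = fit$objective, success = fit$success,
         b_residual = fit$b_residual),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  nz <- fit$eigenvalues[fit$eigenvalues != 0]
  idx <- match_eigen(nz, -target_rates)
  write.csv(data.frame(target_rate = target_rates,
                       achieved = abs(nz[idx])),
            paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}
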