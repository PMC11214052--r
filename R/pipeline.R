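#' Run configuration for the end-to-end analysis
#'
#' A single validated document that, together with a seed, fully determines
#' a pipeline run on synthetic data.
#'
#' @param seed integer seed for all stochastic steps.
#' @param noise relative noise SD (fraction of the maximum absolute signal),
#'   default 0.005.
#' @param n_exp number of exponentials in the global fit (default 5).
#' @param times time grid (s).
#' @param model ground-truth model arguments passed to [wt_like_model()].
#' @param fit_schemes whether to run the microscopic-rate scheme fit.
#' @param n_starts_exp,n_starts_scheme multi-start counts.
#' @param out_dir optional directory for CSV/JSON artifacts.
#' @param verbose log stage timings to stderr.
#' @return object of class `"run_config"`.
#' @export
run_config <- function(seed = 1, noise = 0.005, n_exp = 5,
                       times = default_times(), model = list(),
                       fit_schemes = TRUE, n_starts_exp = 8,
                       n_starts_scheme = 8, out_dir = NULL,
                       verbose = FALSE) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed == round(seed),
            noise >= 0, n_exp >= 1, all(times > 0), !is.unsorted(times),
            is.list(model), is.logical(fit_schemes))
  structure(list(seed = as.integer(seed), noise = noise, n_exp = n_exp,
                 times = times, model = model, fit_schemes = fit_schemes,
                 n_starts_exp = n_starts_exp,
                 n_starts_scheme = n_starts_scheme,
                 out_dir = out_dir, verbose = verbose),
            class = "run_config")
}

# visible apparent lifetimes of a model: nonzero eigenvalue groups whose
# combined b-spectra are not spectrally silent
true_apparent_lifetimes <- function(model, silent_tol = 1e-8) {
  sol <- eigen_solve(build_kinetic_matrix(model$scheme))
  bs <- compute_b_spectra(model$basis, sol, model$mapping)
  ev <- attr(bs, "eigenvalues")
  norms <- sqrt(colSums(bs^2))
  keep <- ev != 0 & norms > silent_tol * max(norms)
  sort(1 / abs(ev[keep]))
}

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[photokin] ", fmt), ...))
}

#' Run the full analysis pipeline on synthetic data
#'
#' simulate -> SVD rank -> global exponential fit -> sequential spectra ->
#' composition -> two-/three-cycle partition -> (optionally) Cycle1
#' construction and Cycle2 microscopic-rate fit -> current alignment.
#' All stochastic steps derive from `config$seed`; a rerun with the same
#' config is byte-identical.
#'
#' @param config a [run_config()].
#' @return list with elements `model`, `dataset`, `rank`, `kinetics`,
#'   `sequential`, `composition`, `partition`, `three_cycle`,
#'   `cycle1_scheme`, `cycle2_fit`, `recovered_rates`, `current_alignment`,
#'   `timings`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[stage] <<- t1 - t0
    stage_log(config$verbose, "%s done (%.2f s)", stage, t1 - t0)
    t0 <<- t1
  }
  fail <- function(stage, e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  model <- tryCatch(do.call(wt_like_model, config$model),
                    error = function(e) fail("model", e))
  noiseless <- simulate_absorbance(model, config$times)
  noise_sd <- config$noise * max(abs(noiseless$D))
  dataset <- tryCatch(
    simulate_absorbance(model, config$times, noise_sd = noise_sd,
                        seed = config$seed),
    error = function(e) fail("simulate", e))
  tick("simulate")

  rank <- svd_rank(noiseless)
  kinetics <- tryCatch(
    global_exp_fit(dataset, config$n_exp,
                   n_starts = config$n_starts_exp, seed = config$seed),
    error = function(e) fail("global_exp_fit", e))
  # misfit detection: residual far above the noise floor flags a wrong n_exp
  misfit <- noise_sd > 0 && kinetics$fit_residual > 2 * noise_sd
  tick("global_exp_fit")

  seq_sp <- tryCatch(sequential_from_b(kinetics),
                     error = function(e) fail("sequential_from_b", e))
  comp <- tryCatch(deconvolve_composition(seq_sp, model$basis),
                   error = function(e) fail("deconvolve", e))
  tick("deconvolve")

  partition <- NULL; three <- NULL
  if (ncol(comp$fractions) == 6) {
    partition <- tryCatch(partition_two_cycle(comp),
                          error = function(e) fail("partition", e))
    three <- split_three_cycle(partition)
    tick("partition")
  } else {
    stage_log(config$verbose,
              "partition skipped: %d intermediates (needs 6)",
              ncol(comp$fractions))
  }

  cycle1_scheme <- NULL; cycle2_fit <- NULL; recovered <- NULL
  if (config$fit_schemes && !is.null(partition)) {
    res <- tryCatch(
      fit_parallel_cycles(kinetics, comp, model$basis,
                          k_open = scheme_rate(model, "K1", "O1"),
                          n_starts = config$n_starts_scheme,
                          seed = config$seed),
      error = function(e) fail("fit_scheme", e))
    cycle1_scheme <- res$cycle1_scheme
    cycle2_fit <- res$cycle2_fit
    recovered <- res$rates
    tick("fit_scheme")
  }

  sol <- eigen_solve(build_kinetic_matrix(model$scheme))
  ev <- time_evolution(sol, config$times)
  trace <- simulate_current(ev, model$scheme$conductive,
                            noise_sd = config$noise, seed = config$seed + 1L)
  alignment <- align_current(trace, ev, model$scheme$conductive)
  tick("current")

  out <- list(model = model, dataset = dataset, rank = rank,
              kinetics = kinetics, sequential = seq_sp, composition = comp,
              partition = partition, three_cycle = three,
              cycle1_scheme = cycle1_scheme, cycle2_fit = cycle2_fit,
              recovered_rates = recovered, current_alignment = alignment,
              misfit_flag = misfit, noise_sd = noise_sd, timings = timings)
  if (!is.null(config$out_dir)) write_pipeline_artifacts(out, config$out_dir)
  out
}

# rate of a named transition in a model's combined scheme
scheme_rate <- function(model, from, to) {
  tr <- model$scheme$transitions
  r <- tr$rate[tr$from == from & tr$to == to]
  if (!length(r)) stop(sprintf("no %s -> %s transition", from, to))
  r[1]
}

#' Construct Cycle1 and fit Cycle2 microscopic rates from recovered data
#'
#' Builds the conductive cycle from the recovered composition (conductive
#' fraction `a4` from In4, slow conductive fraction `a5` from In5, branch
#' rates by [branch_rates()] with the early-ms apparent rate, slow recovery
#' at the late-ms rate, channel-opening rate supplied from the current),
#' subtracts its b-spectra contribution ([cycle2_target_b()]) and fits the
#' nonconductive cycle's equilibration-block rates.
#'
#' Shared-state allocation follows the all-to-Cycle2 default: Cycle1's fast
#' O1 decay goes to O2 and directly to R.
#'
#' @param kinetics recovered [global_exp_fit()] result (5 exponentials).
#' @param comp recovered [composition_matrix()].
#' @param basis spectral basis.
#' @param k_open channel-opening rate (s^-1), an explicit input borrowed
#'   from current measurements (the K -> O step is spectrally silent).
#' @param n_starts,seed scheme-fit multi-start controls.
#' @return list with `cycle1_scheme`, `cycle2_fit`, `rates` (named vector of
#'   all recovered microscopic rates), `bsf`.
#' @export
fit_parallel_cycles <- function(kinetics, comp, basis, k_open,
                                n_starts = 8, seed = 1) {
  stopifnot(length(kinetics$lifetimes) == 5)
  tau <- kinetics$lifetimes
  k_app <- 1 / tau
  k4 <- k_app[4]; k5 <- k_app[5]
  M <- comp$fractions
  a4 <- M["K-like", 4]; a5 <- M["K-like", 5]
  b5 <- M["L-like", 5]; c5 <- M["M", 5]; d5 <- M["R", 5]
  b1 <- branch_rates(k4, c(O2 = a5, R1 = a4 - a5))
  cycle1 <- kinetic_scheme(
    c("K1", "O1", "O2", "R1"),
    data.frame(from = c("K1", "O1", "O1", "O2"),
               to = c("O1", "O2", "R1", "R1"),
               rate = c(k_open, b1[["O2"]], b1[["R1"]], k5)),
    conductive = c("O1", "O2"),
    initial = c(K1 = a4))
  map1 <- c(K1 = "K-like", O1 = "K-like", O2 = "K-like", R1 = "R")
  sol1 <- eigen_solve(build_kinetic_matrix(cycle1))
  bsf <- cycle2_target_b(b_matrix(kinetics), sol1, basis, map1)
  # N1 branch: shared N2/M plus Cycle2's early-recovered R
  # (In5 R content minus Cycle1's fast direct recovery)
  r2_early <- max(d5 - (a4 - a5), 0)
  b2 <- branch_rates(k4, c(N2 = b5, M = c5, R = r2_early))
  topo <- topo_cycle2_branching(initial = c(K = 1 - a4))
  center <- c(k_kl1 = k_app[1] / 2, k_l1k = k_app[1] / 2,
              k_kl2 = k_app[2] / 2, k_l2k = k_app[2] / 2,
              k_l2n1 = 3 * k_app[3])
  fit <- fit_scheme_rates(
    topo, target_rates = k_app, target_b = bsf, basis = basis,
    fixed_rates = c(k_n1_n2 = unname(b2[["N2"]]),
                    k_n1_m = unname(b2[["M"]]),
                    k_n1_r = unname(b2[["R"]]),
                    k_slow = k5),
    n_starts = n_starts, seed = seed, start_center = center,
    # L1/L2 are isospectral: by convention L1 carries the faster equilibrium
    accept = function(r) r[["k_kl1"]] + r[["k_l1k"]] >=
      r[["k_kl2"]] + r[["k_l2k"]])
  rates <- c(fit$free,
             k_o1_o2 = unname(b1[["O2"]]), k_o1_r = unname(b1[["R1"]]),
             k_n1_n2 = unname(b2[["N2"]]), k_n1_m = unname(b2[["M"]]),
             k_n1_r = unname(b2[["R"]]), k_slow = k5)
  list(cycle1_scheme = cycle1, cycle2_fit = fit, rates = rates, bsf = bsf)
}

# true microscopic rates of the default model in recovered-rate naming
true_rates_named <- function(model) {
  g <- function(from, to) scheme_rate(model, from, to)
  c(k_kl1 = g("K2", "L1"), k_l1k = g("L1", "K2"),
    k_kl2 = g("K2", "L2"), k_l2k = g("L2", "K2"),
    k_l2n1 = g("L2", "N1"),
    k_o1_o2 = g("O1", "O2"), k_o1_r = g("O1", "R1"),
    k_n1_n2 = g("N1", "N2"), k_n1_m = g("N1", "M"),
    k_n1_r = g("N1", "R2"), k_slow = g("O2", "R1"))
}

#' Parameter-recovery experiment across seeds
#'
#' Repeats the pipeline on independently seeded noisy datasets and reports
#' the distribution of relative errors for the apparent lifetimes, the
#' composition-matrix entries, and the identifiable microscopic rates.  The
#' spectrally silent channel-opening rate is excluded from scoring: it is
#' not identifiable from spectra and enters only as an input.
#'
#' @param config a [run_config()]; its `seed` seeds the first replicate.
#' @param n_seeds number of replicates (>= 1).
#' @return object of class `"recovery_report"`: `lifetimes` (true,
#'   per-seed recovered, relative errors), `composition` (true matrix,
#'   per-seed max abs error), `rates` (true, per-seed recovered, relative
#'   errors), medians and pass flags.
#' @export
recovery_experiment <- function(config, n_seeds = 20) {
  stopifnot(n_seeds >= 1)
  model <- do.call(wt_like_model, config$model)
  tau_true <- true_apparent_lifetimes(model)
  noiseless <- simulate_absorbance(model, config$times)
  kin0 <- global_exp_fit(noiseless, config$n_exp, n_starts = 2, seed = 1)
  comp_true <- deconvolve_composition(sequential_from_b(kin0), model$basis)
  rates_true <- true_rates_named(model)

  tau_rec <- matrix(NA_real_, n_seeds, length(tau_true))
  comp_err <- numeric(n_seeds)
  rate_rec <- matrix(NA_real_, n_seeds, length(rates_true),
                     dimnames = list(NULL, names(rates_true)))
  for (i in seq_len(n_seeds)) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    cfg$out_dir <- NULL
    res <- run_pipeline(cfg)
    tau_rec[i, ] <- res$kinetics$lifetimes
    comp_err[i] <- max(abs(res$composition$fractions - comp_true$fractions))
    if (!is.null(res$recovered_rates)) {
      rate_rec[i, names(rates_true)] <- res$recovered_rates[names(rates_true)]
    }
  }
  tau_err <- sweep(tau_rec, 2, tau_true, "/") - 1
  rate_err <- sweep(rate_rec, 2, rates_true, "/") - 1
  structure(list(
    lifetimes = list(true = tau_true, recovered = tau_rec,
                     rel_error = tau_err,
                     median_abs = apply(abs(tau_err), 2, stats::median)),
    composition = list(true = comp_true$fractions, max_abs_error = comp_err),
    rates = list(true = rates_true, recovered = rate_rec,
                 rel_error = rate_err,
                 median_abs = stats::median(abs(rate_err), na.rm = TRUE)),
    pass = list(
      lifetimes_within_10pct = all(abs(tau_err) < 0.10),
      composition_within_0.03 = all(comp_err < 0.03),
      rates_median_within_10pct =
        stats::median(abs(rate_err), na.rm = TRUE) < 0.10),
    n_seeds = n_seeds),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d seeds\n", x$n_seeds))
  cat("  lifetime median |rel error|:",
      paste(signif(x$lifetimes$median_abs, 3), collapse = ", "), "\n")
  cat(sprintf("  composition max abs error: %.4f (worst seed)\n",
              max(x$composition$max_abs_error)))
  cat(sprintf("  rate median |rel error|: %.4f\n", x$rates$median_abs))
  for (nm in names(x$pass)) cat(sprintf("  %s: %s\n", nm, x$pass[[nm]]))
  invisible(x)
}

# write the pipeline artifacts (CSV/JSON) under a directory
write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_dataset_csv(res$dataset, p("dataset.csv"))
  write_basis_csv(res$model$basis, p("basis.csv"))
  write_composition_csv(res$composition, p("composition.csv"))
  kin <- list(lifetimes_s = res$kinetics$lifetimes,
              fit_residual = res$kinetics$fit_residual,
              svd_rank = as.integer(res$rank),
              misfit_flag = res$misfit_flag)
  if (!is.null(res$partition)) {
    kin$conductive_fraction <- res$partition$conductive_fraction
    kin$o1 <- res$three_cycle$o1
    kin$o2 <- res$three_cycle$o2
  }
  jsonlite::write_json(kin, p("kinetics.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(res$partition)) {
    jsonlite::write_json(
      list(cycle1 = as.data.frame(res$partition$cycle1),
           cycle2 = as.data.frame(res$partition$cycle2),
           shared = as.data.frame(res$partition$shared),
           meta = res$partition$meta),
      p("partition.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$cycle2_fit)) {
    write_fit_result(res$cycle2_fit, p("cycle2_fit"),
                     1 / res$kinetics$lifetimes)
  }
  invisible(out_dir)
}
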