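# run code with a temporary RNG state derived from `seed`
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Ground-truth parallel two-cycle model (wild-type-like)
#'
#' A conductive cycle (fraction `conductive`, default 0.51 matching a
#' photocurrent plateau of 0.51) running in parallel with a nonconductive
#' cycle (0.49).  The conductive cycle is `K1 -> O1 -> {O2, R}` with
#' `O2 -> R`; the K1 -> O1 channel-opening step converts between two K-like
#' states and so produces no absorbance change of its own, and its rate is
#' conventionally taken from the current rise rather than from spectra.  By
#' default the opening rate is set exactly equal to the nonconductive
#' cycle's third apparent rate, so the two components are degenerate and
#' combine: the synthetic data then contain exactly five observable
#' lifetimes and the opening rate cannot be determined independently from
#' the optical data, only from the current.  (With an isolated opening
#' rate, the downstream O1 -> R conversion would expose it as a weak sixth
#' exponential of relative amplitude ~ `k_app4 / k_open`.)  The
#' nonconductive cycle equilibrates
#' `L1 <-> K2 <-> L2`, drains `L2 -> N1`, and `N1` branches into `N2`, `M`
#' and early-recovered `R` before the slow final recovery.  Branch rates
#' obey [branch_rates()] with the early-ms apparent rate; all slow recovery
#' steps share the late-ms apparent rate, so the two cycles produce
#' degenerate eigenvalues there.  The five observable lifetimes span
#' roughly 0.25 us, 4.5 us, 120 us, 2 ms and 100 ms.
#'
#' @param conductive conductive fraction (photocurrent plateau), default 0.51.
#' @param o2_fraction fraction surviving the fast O1 decay as the slow
#'   conductive O2 state, default 0.14.
#' @param n1_products named fractions of the N1 branching products
#'   (`N2`, `M`, `Rearly`); scaled to the nonconductive fraction.
#' @param k_open K1 -> O1 channel-opening rate (s^-1); `NULL` (default)
#'   sets it equal to the nonconductive cycle's third apparent rate
#'   (~8700 s^-1, a ~115 us rise in the In3--In4 window).
#' @param k_app4,k_app5 early-ms and late-ms apparent rates (s^-1).
#' @param k_eq rates of the fast equilibration block: named vector with
#'   `KL1`, `L1K`, `KL2`, `L2K`, `L2N1`.
#' @return list of class `"photocycle_model"` with `scheme` (combined),
#'   `cycles` (list of per-cycle schemes), `mapping` (state -> form),
#'   `basis`, `conductive_fraction`.
#' @export
wt_like_model <- function(conductive = 0.51,
                          o2_fraction = 0.14,
                          n1_products = c(N2 = 0.19, M = 0.10, Rearly = 0.20),
                          k_open = NULL,
                          k_app4 = 500, k_app5 = 10,
                          k_eq = c(KL1 = 2e6, L1K = 2e6, KL2 = 1e5,
                                   L2K = 1e5, L2N1 = 3e4),
                          basis = default_basis()) {
  noncond <- 1 - conductive
  stopifnot(conductive >= 0, conductive <= 1,
            o2_fraction >= 0, o2_fraction <= conductive,
            abs(sum(n1_products) - noncond) < 1e-9)
  b2 <- branch_rates(k_app4, n1_products)
  cycle2 <- kinetic_scheme(
    states = c("K2", "L1", "L2", "N1", "N2", "M", "R2"),
    transitions = data.frame(
      from = c("K2", "L1", "K2", "L2", "L2", "N1", "N1", "N1", "N2", "M"),
      to   = c("L1", "K2", "L2", "K2", "N1", "N2", "M", "R2", "R2", "R2"),
      rate = c(k_eq[["KL1"]], k_eq[["L1K"]], k_eq[["KL2"]], k_eq[["L2K"]],
               k_eq[["L2N1"]], b2[["N2"]], b2[["M"]], b2[["Rearly"]],
               k_app5, k_app5)),
    initial = c(K2 = noncond))
  if (is.null(k_open)) {
    # degenerate-by-design: opening coincides with the third apparent rate
    ev2 <- eigen(unclass(build_kinetic_matrix(cycle2)),
                 only.values = TRUE)$values
    k_open <- sort(abs(Re(ev2)), decreasing = TRUE)[3]
  }
  b1 <- branch_rates(k_app4, c(O2 = o2_fraction,
                               R1 = conductive - o2_fraction))
  cycle1 <- kinetic_scheme(
    states = c("K1", "O1", "O2", "R1"),
    transitions = data.frame(
      from = c("K1", "O1", "O1", "O2"),
      to   = c("O1", "O2", "R1", "R1"),
      rate = c(k_open, b1[["O2"]], b1[["R1"]], k_app5)),
    conductive = c("O1", "O2"),
    initial = c(K1 = conductive))
  mapping <- c(K1 = "K-like", O1 = "K-like", O2 = "K-like", R1 = "R",
               K2 = "K-like", L1 = "L-like", L2 = "L-like", N1 = "L-like",
               N2 = "L-like", M = "M", R2 = "R")
  structure(
    list(scheme = combine_schemes(cycle1, cycle2),
         cycles = list(cycle1 = cycle1, cycle2 = cycle2),
         mapping = mapping, basis = basis,
         conductive_fraction = conductive),
    class = "photocycle_model")
}

#' @export
print.photocycle_model <- function(x, ...) {
  cat(sprintf("<photocycle_model> %d parallel cycle(s), conductive fraction %.2f\n",
              length(x$cycles), x$conductive_fraction))
  invisible(x)
}

# aggregate state concentrations to spectral-form concentrations
form_concentrations <- function(evolution, mapping, forms) {
  conc <- evolution$concentrations
  out <- vapply(forms, function(f) {
    cols <- names(mapping)[mapping == f]
    cols <- intersect(cols, colnames(conc))
    if (!length(cols)) return(numeric(nrow(conc)))
    rowSums(conc[, cols, drop = FALSE])
  }, numeric(nrow(conc)))
  matrix(out, ncol = length(forms), dimnames = list(NULL, forms))
}

#' Simulate a time-resolved absorbance matrix
#'
#' Forward model of the flash-photolysis measurement: the data matrix is
#' `D = E C_f^T + noise`, where `C_f` aggregates the state concentrations of
#' all parallel cycles onto their spectral forms.  The model is linear, so
#' parallel cycles simply sum.
#'
#' @param model a [wt_like_model()]-style object (scheme, mapping, basis).
#' @param times time grid (s), default [default_times()].
#' @param noise_sd additive i.i.d. Gaussian noise SD (absorbance units), or
#'   a per-wavelength vector for heteroscedastic noise.
#' @param seed integer seed; required whenever `noise_sd > 0`.
#' @return object of class `"synthetic_dataset"`: list with `grid`, `times`,
#'   `D` (n_wavelengths x n_times), `noise_sd`, `seed`, `ground_truth`.
#' @export
simulate_absorbance <- function(model, times = default_times(),
                                noise_sd = 0, seed = NULL) {
  stopifnot(inherits(model, "photocycle_model"), all(noise_sd >= 0))
  if (any(noise_sd > 0) && is.null(seed)) {
    stop("`seed` is required for noisy simulations")
  }
  sol <- eigen_solve(build_kinetic_matrix(model$scheme))
  ev <- time_evolution(sol, times)
  Cf <- form_concentrations(ev, model$mapping, colnames(model$basis$E))
  D <- model$basis$E %*% t(Cf)
  if (any(noise_sd > 0)) {
    noise <- with_seed(seed,
      matrix(rnorm(length(D)), nrow(D), ncol(D)))
    D <- D + noise * noise_sd   # recycles per-wavelength SD down columns
  }
  structure(
    list(grid = model$basis$grid, times = times, D = D,
         noise_sd = noise_sd, seed = seed, ground_truth = model),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d wavelengths x %d times, noise sd %.3g\n",
    nrow(x$D), ncol(x$D), max(x$noise_sd)))
  invisible(x)
}

#' Simulate a photocurrent trace from a time evolution
#'
#' The channel current follows the summed populations of the conductive
#' states: `I(t) = scale * sum_conductive c_i(t) + noise`.
#'
#' @param evolution a [time_evolution()] result.
#' @param conductive_flags character vector of conductive state names (or
#'   named logical).
#' @param scale current scale factor (plateau of the reference condition is
#'   conventionally normalized to the conductive fraction).
#' @param noise_sd additive Gaussian noise SD.
#' @param seed integer seed, required when `noise_sd > 0`.
#' @return object of class `"current_trace"`: list with `times`, `current`.
#' @export
simulate_current <- function(evolution, conductive_flags, scale = 1,
                             noise_sd = 0, seed = NULL) {
  stopifnot(inherits(evolution, "time_evolution"))
  if (is.logical(conductive_flags)) {
    conductive_flags <- names(conductive_flags)[conductive_flags]
  }
  cols <- intersect(conductive_flags, colnames(evolution$concentrations))
  cur <- if (length(cols)) {
    scale * rowSums(evolution$concentrations[, cols, drop = FALSE])
  } else {
    numeric(length(evolution$times))
  }
  if (noise_sd > 0) {
    if (is.null(seed)) stop("`seed` is required for noisy simulations")
    cur <- cur + with_seed(seed, rnorm(length(cur), sd = noise_sd))
  }
  structure(list(times = evolution$times, current = cur),
            class = "current_trace")
}

#' Write / read a synthetic dataset as CSV + JSON sidecar
#'
#' The matrix goes to CSV (first column `wavelength_nm`, remaining columns
#' one per time point) and the metadata (times, noise SD, seed) to a JSON
#' sidecar next to it.
#'
#' @param dataset a [simulate_absorbance()] result.
#' @param path CSV path.
#' @return `path` invisibly (`write`), or a list with `grid`, `times`, `D`
#'   (`read`).
#' @export
write_dataset_csv <- function(dataset, path) {
  df <- data.frame(wavelength_nm = dataset$grid$wavelength, dataset$D,
                   check.names = FALSE)
  names(df)[-1] <- sprintf("t%d", seq_along(dataset$times))
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(times_s = dataset$times, noise_sd = dataset$noise_sd,
         seed = dataset$seed),
    paste0(sub("\\.csv$", "", path), ".json"),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(sub("\\.csv$", "", path), ".json"),
                              simplifyVector = TRUE)
  wl <- df$wavelength_nm
  list(grid = wavelength_grid(min(wl), max(wl), length(wl)),
       times = as.numeric(meta$times_s),
       D = as.matrix(df[, -1, drop = FALSE]))
}

#' Write a current trace as CSV
#'
#' @param trace a [simulate_current()] result.
#' @param path CSV path (columns `time_s`, `current`).
#' @return `path`, invisibly.
#' @export
write_current_csv <- function(trace, path) {
  write.csv(data.frame(time_s = trace$times, current = trace$current),
            path, row.names = FALSE)
  invisible(path)
}
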