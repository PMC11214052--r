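#' Photocurrent exponential components
#'
#' @param rise `c(amplitude, lifetime)`; the rising phase carries a negative
#'   amplitude in the exponential-sum representation.
#' @param fast_decay,slow_decay `c(amplitude, lifetime)` of the two decay
#'   phases (open-channel states O1 and O2 correspond to the fast and slow
#'   current decays).
#' @param baseline constant offset.
#' @return object of class `"current_components"`.
#' @export
current_components <- function(rise = c(amplitude = 0, lifetime = NA),
                               fast_decay = c(amplitude = 0, lifetime = NA),
                               slow_decay = c(amplitude = 0, lifetime = NA),
                               baseline = 0) {
  comp <- list(rise = rise, fast_decay = fast_decay,
               slow_decay = slow_decay, baseline = baseline)
  for (nm in c("rise", "fast_decay", "slow_decay")) {
    lt <- comp[[nm]][["lifetime"]]
    if (!is.na(lt) && lt <= 0) stop(nm, " lifetime must be positive")
  }
  structure(comp, class = "current_components")
}

#' @export
print.current_components <- function(x, ...) {
  fmt <- function(nm) sprintf("  %-10s amplitude %8.4g  lifetime %8.4g s\n",
                              nm, x[[nm]][["amplitude"]],
                              x[[nm]][["lifetime"]])
  cat("<current_components>\n", fmt("rise"), fmt("fast_decay"),
      fmt("slow_decay"), sprintf("  baseline %.4g\n", x$baseline), sep = "")
  invisible(x)
}

#' Synthesize a current trace from components
#'
#' @param components a [current_components()].
#' @param times time grid (s).
#' @return a `"current_trace"` object.
#' @export
current_from_components <- function(components, times) {
  cur <- rep(components$baseline, length(times))
  for (nm in c("rise", "fast_decay", "slow_decay")) {
    cc <- components[[nm]]
    if (!is.na(cc[["lifetime"]]) && cc[["amplitude"]] != 0) {
      cur <- cur + cc[["amplitude"]] * exp(-times / cc[["lifetime"]])
    }
  }
  structure(list(times = times, current = cur), class = "current_trace")
}

#' Decompose a photocurrent trace into exponential components
#'
#' Fits an exponential sum plus baseline by variable projection (lifetimes
#' optimized in log space, amplitudes linear with free sign).  The
#' negative-amplitude component is reported as the rise; positive-amplitude
#' components are the fast and slow decays, ordered by lifetime.
#'
#' @param trace a `"current_trace"` (list with `times`, `current`).
#' @param n_components number of exponentials (default 3: one rise plus two
#'   decays).
#' @param n_starts,seed multi-start controls as in [global_exp_fit()].
#' @return a [current_components()] with attributes `"residual"` (RMS) and
#'   `"lifetimes"` (all fitted lifetimes).
#' @export
decompose_current <- function(trace, n_components = 3, n_starts = 8,
                              seed = 1) {
  times <- trace$times
  y <- trace$current
  if (max(abs(y)) < 1e-14) {
    out <- current_components(baseline = 0)
    attr(out, "residual") <- 0
    return(out)
  }
  D <- matrix(y, nrow = 1)
  fit <- global_exp_fit(D, n_exp = n_components, times = times,
                        n_starts = n_starts, seed = seed)
  if (fit$convergence != 0 && fit$fit_residual > 0.05 * max(abs(y))) {
    stop(sprintf("current fit failed to converge (RMS residual %.3g)",
                 fit$fit_residual))
  }
  amps <- as.numeric(fit$b_spectra[1, seq_len(n_components)])
  taus <- fit$lifetimes
  baseline <- as.numeric(fit$b_spectra[1, n_components + 1])
  tiny <- 1e-6 * max(abs(y))
  neg <- which(amps < -tiny)
  pos <- which(amps > tiny)
  rise <- if (length(neg)) {
    j <- neg[which.min(taus[neg])]
    c(amplitude = amps[j], lifetime = taus[j])
  } else c(amplitude = 0, lifetime = NA)
  pos <- pos[order(taus[pos])]
  fast <- if (length(pos) >= 1)
    c(amplitude = amps[pos[1]], lifetime = taus[pos[1]])
  else c(amplitude = 0, lifetime = NA)
  slow <- if (length(pos) >= 2)
    c(amplitude = amps[pos[2]], lifetime = taus[pos[2]])
  else c(amplitude = 0, lifetime = NA)
  out <- current_components(rise, fast, slow, baseline)
  attr(out, "residual") <- fit$fit_residual
  attr(out, "lifetimes") <- taus
  out
}

#' Apply amplitude and acceleration factors to current components
#'
#' Each component's amplitude is multiplied by its amplitude factor and its
#' lifetime divided by its time (acceleration) factor, then the trace is
#' re-synthesized on the original time grid.  This is how published current
#' traces recorded under one condition are adapted to another (e.g. fast and
#' slow decays amplitude-corrected by 0.9 and 1.1 and accelerated by 1.7 and
#' 1.6 to match optical data).
#'
#' @param components a [current_components()].
#' @param factors list with named numeric `amplitude` and `time` entries for
#'   any of `rise`, `fast_decay`, `slow_decay`; missing entries default to 1.
#'   All factors must be positive.
#' @param times time grid for the re-synthesized trace.
#' @return list with `components` (modified) and `trace`.
#' @export
modify_current <- function(components, factors, times) {
  get1 <- function(what, nm) {
    v <- factors[[what]]
    if (is.null(v) || is.null(v[nm]) || is.na(v[nm])) 1 else unname(v[nm])
  }
  out <- components
  for (nm in c("rise", "fast_decay", "slow_decay")) {
    fa <- get1("amplitude", nm); ft <- get1("time", nm)
    if (fa <= 0 || ft <= 0) stop("modification factors must be positive")
    out[[nm]][["amplitude"]] <- components[[nm]][["amplitude"]] * fa
    if (!is.na(out[[nm]][["lifetime"]])) {
      out[[nm]][["lifetime"]] <- components[[nm]][["lifetime"]] / ft
    }
  }
  list(components = out, trace = current_from_components(out, times))
}

#' Align a current trace with conductive-state concentrations
#'
#' Finds the single nonnegative scale minimizing the squared residual
#' between the current and the summed conductive-state populations; the
#' alignment is shape-based (absolute current units are arbitrary).
#'
#' @param trace a `"current_trace"`.
#' @param evolution a [time_evolution()] on the same time grid.
#' @param conductive_flags conductive state names (or named logical).
#' @return list with `scale`, `residual` (RMS of `trace - scale * conc`),
#'   `normalized_residual` (RMS over the conductive-sum RMS), `plateau`
#'   (maximum of the scaled conductive sum).
#' @export
align_current <- function(trace, evolution, conductive_flags) {
  if (is.logical(conductive_flags)) {
    conductive_flags <- names(conductive_flags)[conductive_flags]
  }
  cols <- intersect(conductive_flags, colnames(evolution$concentrations))
  if (!length(cols)) stop("no conductive state in the model")
  stopifnot(length(trace$times) == length(evolution$times),
            all(abs(log(trace$times / evolution$times)) < 1e-9))
  conc <- rowSums(evolution$concentrations[, cols, drop = FALSE])
  scale <- max(0, sum(trace$current * conc) / sum(conc^2))
  resid <- trace$current - scale * conc
  list(scale = scale,
       residual = sqrt(mean(resid^2)),
       normalized_residual = sqrt(mean(resid^2)) / sqrt(mean((scale * conc)^2)),
       plateau = max(scale * conc))
}

#' Fast-component modification required to align a current to a profile
#'
#' For conditions where the reference current cannot follow the red-shifted
#' spectral-form profile (its two slowest decays separated far more than the
#' usual ~10x between current components), this fits the amplitude and
#' acceleration factors of the fast decay component (slow component and
#' baseline held fixed) that best align the re-synthesized current with the
#' profile.  A required acceleration far above 1 signals that the alignment
#' is unrealistic and that the conductive state behind the fast decay is
#' absent.
#'
#' @param components reference-current [current_components()].
#' @param profile numeric target profile (e.g. the K-like spectral-form
#'   concentration trace).
#' @param times time grid of `profile`.
#' @return list with `time_factor` (acceleration of the fast component),
#'   `amplitude_factor`, `residual` (RMS at the optimum).
#' @export
required_fast_modification <- function(components, profile, times) {
  stopifnot(length(profile) == length(times))
  obj <- function(p) {
    mod <- modify_current(components,
                          list(amplitude = c(fast_decay = exp(p[1])),
                               time = c(fast_decay = exp(p[2]))),
                          times)
    sum((mod$trace$current - profile)^2)
  }
  fit <- optim(c(0, 0), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  list(amplitude_factor = exp(fit$par[1]),
       time_factor = exp(fit$par[2]),
       residual = sqrt(fit$value / length(times)))
}

#' Export current components and modification factors as JSON
#'
#' @param components a [current_components()].
#' @param path JSON path.
#' @param factors optional modification-factor list to include.
#' @return `path`, invisibly.
#' @export
write_components_json <- function(components, path, factors = NULL) {
  obj <- list(rise = as.list(components$rise),
              fast_decay = as.list(components$fast_decay),
              slow_decay = as.list(components$slow_decay),
              baseline = components$baseline)
  if (!is.null(factors)) {
    # named vectors must become lists to keep their names in JSON
    obj$factors <- lapply(factors, as.list)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
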