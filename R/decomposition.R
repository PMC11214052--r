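#' Effective rank of a data matrix by singular values
#'
#' Counts singular values above `threshold` times the largest one; on
#' noiseless data generated from `k` independent spectra this equals `k`.
#'
#' @param dataset a [simulate_absorbance()] result, or a plain matrix.
#' @param threshold relative singular-value cutoff (default 1e-6).
#' @return integer rank estimate, with the singular values attached as
#'   attribute `"singular_values"`.
#' @export
svd_rank <- function(dataset, threshold = 1e-6) {
  D <- if (inherits(dataset, "synthetic_dataset")) dataset$D else dataset
  stopifnot(is.matrix(D), length(D) > 0)
  sv <- svd(D, nu = 0, nv = 0)$d
  structure(sum(sv > threshold * sv[1]), singular_values = sv)
}

# variable-projection residual: D ~ B X(tau)^T with X = [exp(-t/tau), 1]
varpro_design <- function(times, lifetimes) {
  cbind(exp(-outer(times, 1 / lifetimes)), 1)
}

varpro_solve <- function(D, times, lifetimes) {
  X <- varpro_design(times, lifetimes)
  coef <- tryCatch(qr.solve(X, t(D)), error = function(e) NULL)
  if (is.null(coef)) return(list(rss = Inf, B = NULL))
  R <- t(D) - X %*% coef
  list(rss = sum(R^2), B = t(coef))
}

#' Global multi-exponential fit of a time-resolved data matrix
#'
#' Fits `D(lambda, t) = sum_j b_j(lambda) exp(-t / tau_j) + b_inf(lambda)`
#' globally over all wavelengths by variable projection: the lifetimes are
#' optimized in log space (Nelder-Mead, multi-start) while the amplitude
#' b-spectra are obtained from the exact linear solve at each step.  The
#' non-decaying spectrum `b_inf` (the final, recovered state) is always
#' included.
#'
#' @param dataset a [simulate_absorbance()] result or plain matrix (then
#'   `times` must be given).
#' @param n_exp number of exponentials (>= 1).
#' @param init_lifetimes optional starting lifetimes (s); default log-spaced
#'   across the observed time window.
#' @param times time grid, taken from the dataset when omitted.
#' @param n_starts number of multi-starts (default 8); starts beyond the
#'   first jitter the initial log-lifetimes deterministically via `seed`.
#' @param seed seed for the start jitter (default 1).
#' @param min_separation smallest allowed ratio between adjacent fitted
#'   lifetimes before a duplicate warning is raised (default 1.5).
#' @return object of class `"apparent_kinetics"`: `lifetimes` (ascending),
#'   `b_spectra` (n_wavelengths x (n_exp + 1), last column `b_inf`),
#'   `fit_residual` (root-mean-square), `times`, `grid` (when available),
#'   `objective` (residual sum of squares), `convergence`.
#' @export
global_exp_fit <- function(dataset, n_exp, init_lifetimes = NULL,
                           times = NULL, n_starts = 8, seed = 1,
                           min_separation = 1.5) {
  if (inherits(dataset, "synthetic_dataset")) {
    D <- dataset$D
    times <- dataset$times
    grid <- dataset$grid
  } else {
    D <- dataset
    grid <- NULL
    if (is.null(times)) stop("`times` required for a plain matrix")
  }
  stopifnot(n_exp >= 1, ncol(D) == length(times))
  span <- range(times)
  if (log10(span[2] / span[1]) < n_exp + 1) {
    stop("time span too short to separate ", n_exp, " lifetimes: ",
         "need roughly two decades of coverage per lifetime sought")
  }
  if (is.null(init_lifetimes)) {
    init_lifetimes <- exp(seq(log(span[1] * 3), log(span[2] / 3),
                              length.out = n_exp))
  }
  stopifnot(length(init_lifetimes) == n_exp)
  obj <- function(logtau) varpro_solve(D, times, exp(logtau))$rss
  starts <- with_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      base <- log(sort(init_lifetimes))
      if (i == 1) base else base + rnorm(n_exp, sd = 0.35)
    })
  })
  best <- NULL
  for (s in starts) {
    fit <- optim(s, obj, method = "Nelder-Mead",
                 control = list(maxit = 3000, reltol = 1e-13))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!is.finite(best$value)) {
    stop("global exponential fit failed to converge; best objective ",
         best$value)
  }
  tau <- sort(exp(best$par))
  if (any(tau[-1] / tau[-n_exp] < min_separation)) {
    warning("fitted lifetimes nearly duplicate; consider reducing n_exp")
  }
  sol <- varpro_solve(D, times, tau)
  colnames(sol$B) <- c(sprintf("b%d", seq_len(n_exp)), "b_inf")
  structure(
    list(lifetimes = tau, b_spectra = sol$B,
         fit_residual = sqrt(sol$rss / length(D)),
         objective = sol$rss, convergence = best$convergence,
         times = times, grid = grid),
    class = "apparent_kinetics")
}

#' @export
print.apparent_kinetics <- function(x, ...) {
  cat(sprintf("<apparent_kinetics> %d exponentials + constant, RMS residual %.3g\n",
              length(x$lifetimes), x$fit_residual))
  cat("  lifetimes (s):", paste(signif(x$lifetimes, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Sequential intermediate spectra from amplitude b-spectra
#'
#' Converts the b-spectra of a global exponential fit into the spectra of
#' the sequential intermediates In1 -> In2 -> ... -> In(n+1), the
#' bookkeeping chain with rates `k_j = 1/tau_j` assigned fastest-first and
#' unit initial population in In1.  The chain is a tool, not the mechanism:
#' its intermediates are mixtures of spectral forms.  With Bateman
#' coefficient matrix `C` (state weights per exponential) the data satisfy
#' `B = S C`, so `S = B C^-1`.
#'
#' @param kinetics an [global_exp_fit()] result (lifetimes must be distinct
#'   and ascending).
#' @param max_condition largest acceptable condition number of the Bateman
#'   coefficient matrix (near-equal rates make it ill-conditioned).
#' @return object of class `"sequential_spectra"`: `spectra`
#'   (n_wavelengths x (n_exp + 1), columns In1..), `rates` (descending),
#'   `grid`.
#' @export
sequential_from_b <- function(kinetics, max_condition = 1e10) {
  stopifnot(inherits(kinetics, "apparent_kinetics"))
  tau <- kinetics$lifetimes
  if (is.unsorted(tau, strictly = TRUE)) {
    stop("lifetimes must be strictly ascending (rates assigned fastest first)")
  }
  n <- length(tau)
  k <- 1 / tau                       # k1 >= k2 >= ... by construction
  states <- sprintf("In%d", seq_len(n + 1))
  chain <- kinetic_scheme(
    states,
    data.frame(from = states[seq_len(n)], to = states[-1], rate = k),
    initial = setNames(1, "In1"))
  sol <- eigen_solve(build_kinetic_matrix(chain))
  # eigenvalues sorted by decreasing magnitude match -k1..-kn, 0 which is
  # exactly the b-spectra column order (ascending lifetime, b_inf last)
  C <- sol$W
  kap <- kappa(C, exact = TRUE)
  if (kap > max_condition) {
    stop(sprintf(
      "near-equal apparent rates: Bateman matrix condition %.3g exceeds %.3g",
      kap, max_condition))
  }
  S <- kinetics$b_spectra %*% solve(C)
  colnames(S) <- states
  structure(list(spectra = S, rates = k, grid = kinetics$grid),
            class = "sequential_spectra")
}

#' Composition matrix (spectral-form fractions per sequential intermediate)
#'
#' @param fractions numeric matrix, rows = spectral forms (conventionally
#'   K-like, L-like, M, R), columns = In1..In6; entries >= 0.
#' @param normalized whether columns were normalized to sum to 1.
#' @return object of class `"composition_matrix"`.
#' @export
composition_matrix <- function(fractions, normalized = TRUE) {
  stopifnot(is.matrix(fractions), all(fractions >= -1e-9))
  if (is.null(rownames(fractions))) {
    stopifnot(nrow(fractions) == 4)
    rownames(fractions) <- c("K-like", "L-like", "M", "R")
  }
  if (is.null(colnames(fractions))) {
    colnames(fractions) <- sprintf("In%d", seq_len(ncol(fractions)))
  }
  structure(list(fractions = fractions, normalized = normalized),
            class = "composition_matrix")
}

#' @export
print.composition_matrix <- function(x, ...) {
  cat("<composition_matrix>\n")
  print(round(x$fractions, 3))
  invisible(x)
}

#' Deconvolve sequential spectra onto a spectral basis
#'
#' Non-negative least squares of every sequential intermediate spectrum on
#' the basis of spectral forms, giving the composition matrix (the fraction
#' of each form contained in each intermediate).
#'
#' @param seq a [sequential_from_b()] result (or plain spectra matrix).
#' @param basis a [build_basis()] object.
#' @param normalize normalize each column to sum to 1 (default TRUE;
#'   sequential-intermediate columns are population fractions).
#' @param max_condition reject bases with condition number above this.
#' @return a [composition_matrix()] with per-column residuals in attribute
#'   `"residuals"` and raw (unnormalized) weights in attribute `"weights"`.
#' @export
deconvolve_composition <- function(seq, basis, normalize = TRUE,
                                   max_condition = 1e8) {
  S <- if (inherits(seq, "sequential_spectra")) seq$spectra else seq
  stopifnot(inherits(basis, "spectral_basis"), nrow(S) == nrow(basis$E))
  if (basis$condition > max_condition) {
    stop(sprintf("basis condition number %.3g exceeds %.3g",
                 basis$condition, max_condition))
  }
  fits <- apply(S, 2, function(y) pracma::lsqnonneg(basis$E, y),
                simplify = FALSE)
  Wt <- vapply(fits, function(f) f$x, numeric(ncol(basis$E)))
  Wt <- matrix(Wt, nrow = ncol(basis$E),
               dimnames = list(colnames(basis$E), colnames(S)))
  res <- vapply(seq_along(fits), function(j)
    sqrt(sum((S[, j] - basis$E %*% Wt[, j])^2) / nrow(S)), 0)
  frac <- Wt
  if (normalize) {
    cs <- colSums(Wt)
    nz <- cs > 0
    frac[, nz] <- sweep(Wt[, nz, drop = FALSE], 2, cs[nz], "/")
  }
  out <- composition_matrix(frac, normalized = normalize)
  attr(out, "residuals") <- res
  attr(out, "weights") <- Wt
  out
}

#' Write a composition matrix as CSV (rows = forms, columns = In1..)
#'
#' @param comp a [composition_matrix()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_composition_csv <- function(comp, path) {
  df <- data.frame(form = rownames(comp$fractions), comp$fractions,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
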