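#' Build the first-order rate matrix of a scheme
#'
#' The rate matrix `A` satisfies `dc/dt = A c`: entry `A[i, j]` (i != j) is
#' the rate of the `j -> i` transition and each diagonal entry is minus the
#' total outgoing rate of its state, so columns sum to zero (closed system,
#' mass conservation).
#'
#' @param scheme a [kinetic_scheme()].
#' @return object of class `"kinetic_matrix"`: the square matrix `A` (s^-1)
#'   with state dimnames and the scheme attached as attribute `"scheme"`.
#' @export
build_kinetic_matrix <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  n <- length(scheme$states)
  A <- matrix(0, n, n, dimnames = list(scheme$states, scheme$states))
  for (i in seq_len(nrow(scheme$transitions))) {
    tr <- scheme$transitions[i, ]
    A[tr$to, tr$from] <- A[tr$to, tr$from] + tr$rate
  }
  diag(A) <- diag(A) - colSums(A)
  structure(A, class = c("kinetic_matrix", "matrix"), scheme = scheme)
}

#' Eigen-decomposition solution of a first-order kinetic system
#'
#' Solves `dc/dt = A c`, `c(0) = c0` as `c(t) = sum_k W[, k] exp(lambda_k t)`
#' where column `k` of the weight matrix `W` is the `k`-th eigenvector scaled
#' by the projection coefficient of the initial condition.  Eigenvalues are
#' sorted by decreasing magnitude (fastest first, the zero eigenvalue of a
#' closed cycle last) and grouped into degeneracy groups: parallel cycles
#' that share a lifetime produce repeated eigenvalues whose eigenvector
#' weights must be combined before comparison with data.
#'
#' Fully reversible schemes (every transition paired with its reverse,
#' satisfying the Kolmogorov/detailed-balance criterion) are solved through
#' a symmetrizing similarity transform, which guarantees real eigenvalues
#' and an orthogonal eigenbasis even when rates span many decades; other
#' schemes use the general solver, which rejects complex spectra.
#'
#' @param matrix a [build_kinetic_matrix()] result (or plain square matrix).
#' @param c0 initial populations; defaults to the scheme's `initial`.
#' @param degeneracy_tol relative tolerance for grouping equal eigenvalues
#'   (default 1e-9); relative gaps between 1e-9 and `near_tol` raise a
#'   near-degeneracy warning.
#' @param near_tol see above; default 1e-6.
#' @return object of class `"eigen_solution"`: list with `eigenvalues`
#'   (real, <= 0 up to round-off), `W` (states x eigenvalues), `c0`,
#'   `degeneracy_groups` (list of index vectors), `states`.
#' @export
eigen_solve <- function(matrix, c0 = NULL, degeneracy_tol = 1e-9,
                        near_tol = 1e-6) {
  A <- unclass(matrix)
  scheme <- attr(matrix, "scheme")
  states <- rownames(A)
  if (is.null(c0)) {
    if (is.null(scheme)) stop("c0 required when matrix has no attached scheme")
    c0 <- scheme$initial
  }
  stopifnot(length(c0) == nrow(A))
  pi_w <- reversible_weights(A)
  if (!is.null(pi_w)) {
    # detailed-balance symmetrization: S = D^-1/2 A D^1/2 is symmetric
    s <- sqrt(pi_w)
    S <- sweep(sweep(A, 1, s, "/"), 2, s, "*")
    S <- (S + t(S)) / 2
    es <- eigen(S, symmetric = TRUE)
    lambda <- es$values
    V <- es$vectors * s                      # V = D^1/2 U, rows scaled
    coef <- as.numeric(crossprod(es$vectors, as.numeric(c0) / s))
  } else {
    es <- eigen(A)
    if (max(abs(Im(es$values))) > 1e-8 * max(abs(es$values), 1)) {
      stop("complex eigenvalues: irreversible loops are not supported ",
           "(schemes must be chains, trees or reversible networks with ",
           "real spectra)")
    }
    lambda <- Re(es$values)
    V <- Re(es$vectors)
    coef <- NULL
  }
  ord <- order(-abs(lambda))
  lambda <- lambda[ord]
  V <- V[, ord, drop = FALSE]
  if (!is.null(coef)) coef <- coef[ord]
  # snap the stationary eigenvalue of closed cycles to exactly zero;
  # numerical zeros are ~eps * ||A||, so 1e-12 relative leaves genuine
  # slow modes (down to 1e-12 of the fastest rate) untouched
  zero_tol <- 1e-12 * max(abs(lambda), 1)
  lambda[abs(lambda) < zero_tol] <- 0
  if (is.null(coef)) {
    kap <- tryCatch(kappa(V, exact = TRUE), error = function(e) Inf)
    coef <- tryCatch(solve(V, as.numeric(c0)), error = function(e) NULL)
    if (is.null(coef) || kap > 1e10) {
      # name the closest eigenvalue pair for diagnosis
      d <- abs(outer(lambda, lambda, "-")) /
        pmax(abs(outer(lambda, lambda, "+")) / 2, 1e-300)
      diag(d) <- Inf
      ij <- which(d == min(d), arr.ind = TRUE)[1, ]
      stop(sprintf(
        "defective (non-diagonalizable) kinetic matrix near eigenvalues %.6g and %.6g",
        lambda[ij[1]], lambda[ij[2]]))
    }
  }
  W <- V * rep(coef, each = nrow(V))
  rownames(W) <- states
  # degeneracy grouping on sorted eigenvalues
  scale <- pmax(abs(lambda), 1e-300)
  groups <- list()
  gi <- 1L
  for (k in seq_along(lambda)) {
    if (k > 1) {
      rel <- abs(lambda[k] - lambda[k - 1]) /
        max(abs(lambda[k]), abs(lambda[k - 1]), 1e-300)
      if (lambda[k] == 0 && lambda[k - 1] == 0) rel <- 0
      if (rel < degeneracy_tol) {
        groups[[gi - 1L]] <- c(groups[[gi - 1L]], k)
        next
      }
      if (rel < near_tol) {
        warning(sprintf(
          "near-degenerate eigenvalues %.6g and %.6g (relative gap %.2g)",
          lambda[k - 1], lambda[k], rel))
      }
    }
    groups[[gi]] <- k
    gi <- gi + 1L
  }
  sol <- structure(
    list(eigenvalues = lambda, W = W, c0 = as.numeric(c0),
         degeneracy_groups = groups, states = states, scheme = scheme),
    class = "eigen_solution")
  recon <- rowSums(W)
  if (max(abs(recon - as.numeric(c0))) > 1e-8 * max(abs(c0), 1)) {
    stop("eigen-solution failed to reconstruct the initial condition")
  }
  sol
}

#' @export
print.eigen_solution <- function(x, ...) {
  cat(sprintf("<eigen_solution> %d states\n", length(x$states)))
  tau <- ifelse(x$eigenvalues == 0, Inf, -1 / x$eigenvalues)
  cat("  eigenvalues (s^-1):", paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  cat("  lifetimes (s):     ", paste(signif(tau, 4), collapse = ", "), "\n")
  if (any(lengths(x$degeneracy_groups) > 1)) {
    cat("  degenerate groups:",
        paste(vapply(Filter(function(g) length(g) > 1, x$degeneracy_groups),
                     function(g) paste(g, collapse = "+"), ""), collapse = "; "),
        "\n")
  }
  invisible(x)
}

#' Default log-spaced time grid
#'
#' 200 points from 100 ns to 1 s, the window of the time-resolved
#' absorption experiments this package emulates.
#'
#' @param from,to time limits in seconds.
#' @param n number of points.
#' @return numeric vector of times (s).
#' @export
default_times <- function(from = 1e-7, to = 1, n = 200) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Evaluate state concentrations over time
#'
#' @param solution an [eigen_solve()] result.
#' @param times positive, sorted times (s).
#' @return object of class `"time_evolution"`: list with `times` and
#'   `concentrations` (n_times x n_states matrix, state-named columns).
#' @export
time_evolution <- function(solution, times = default_times()) {
  stopifnot(inherits(solution, "eigen_solution"),
            all(times > 0), !is.unsorted(times))
  Et <- exp(outer(times, solution$eigenvalues))      # n_times x n_eig
  conc <- Et %*% t(solution$W)                       # n_times x n_states
  colnames(conc) <- solution$states
  structure(list(times = times, concentrations = conc),
            class = "time_evolution")
}

#' Amplitude b-spectra of an eigen-solution
#'
#' The b-spectra are `bs = E x W` with eigenvector weights belonging to
#' degenerate eigenvalues combined first, so parallel cycles sharing a
#' lifetime contribute a single spectrum per observable exponential.  The
#' spectrum of the zero eigenvalue is the final (recovered) spectrum.
#' Transitions between isospectral states are spectrally silent: their
#' eigencomponent has (numerically) zero b-spectrum.
#'
#' @param basis a [build_basis()] object.
#' @param solution an [eigen_solve()] result.
#' @param state_to_form named character: for every state, the name of its
#'   spectral form (a column of `basis$E`).
#' @return matrix (n_wavelengths x n_groups) with attribute
#'   `"eigenvalues"` (one representative per degeneracy group).
#' @export
compute_b_spectra <- function(basis, solution, state_to_form) {
  stopifnot(inherits(basis, "spectral_basis"),
            inherits(solution, "eigen_solution"))
  missing <- setdiff(solution$states, names(state_to_form))
  if (length(missing)) {
    stop("unmapped state(s): ", paste(missing, collapse = ", "))
  }
  forms <- colnames(basis$E)
  bad <- setdiff(unique(state_to_form[solution$states]), forms)
  if (length(bad)) stop("mapping uses unknown form(s): ", paste(bad, collapse = ", "))
  # form x state aggregation matrix
  FS <- vapply(solution$states,
               function(s) as.numeric(forms == state_to_form[[s]]),
               numeric(length(forms)))
  FS <- matrix(FS, nrow = length(forms),
               dimnames = list(forms, solution$states))
  groups <- solution$degeneracy_groups
  bs <- vapply(groups, function(g) {
    w <- rowSums(solution$W[, g, drop = FALSE])
    as.numeric(basis$E %*% (FS %*% w))
  }, numeric(nrow(basis$E)))
  bs <- matrix(bs, ncol = length(groups))
  attr(bs, "eigenvalues") <- vapply(groups, function(g)
    solution$eigenvalues[g[1]], 0)
  bs
}

# Detailed-balance weights of a reversible rate matrix, or NULL.
#
# Returns a positive vector `pi` with `pi[j] * A[i, j] == pi[i] * A[j, i]`
# for every transition pair when the scheme is fully reversible (every
# off-diagonal rate has a nonzero reverse) and satisfies the Kolmogorov
# criterion on loops; returns NULL otherwise.  `diag(pi)^-1/2 A diag(pi)^1/2`
# is then symmetric, so the spectrum is provably real.
reversible_weights <- function(A) {
  n <- nrow(A)
  off <- A
  diag(off) <- 0
  sup <- off > 0
  if (!identical(sup, t(sup))) return(NULL)
  w <- rep(NA_real_, n)
  for (start in seq_len(n)) {
    if (!is.na(w[start])) next
    w[start] <- 1
    queue <- start
    while (length(queue)) {
      i <- queue[[1]]
      queue <- queue[-1]
      for (j in which(sup[, i])) {
        if (is.na(w[j])) {
          # w_j * k(j->i) = w_i * k(i->j):  A[i,j] w_j = A[j,i] w_i
          w[j] <- w[i] * off[j, i] / off[i, j]
          queue <- c(queue, j)
        }
      }
    }
  }
  if (!all(is.finite(w)) || any(w <= 0)) return(NULL)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && sup[i, j]) {
        lhs <- off[i, j] * w[j]
        rhs <- off[j, i] * w[i]
        if (abs(lhs - rhs) > 1e-10 * (lhs + rhs)) return(NULL)
      }
    }
  }
  w
}

#' Branch rates from an apparent rate and product fractions
#'
#' In an irreversible branching step, the overall apparent rate is the sum
#' of the individual branch rates, so each branch rate is the apparent rate
#' weighted by its relative product yield:
#' `k_i = k_app * fr_i / sum(fr)`.
#'
#' @param k_app overall apparent rate of the branching step (s^-1, > 0).
#' @param fractions nonnegative product fractions, at least one positive.
#' @return numeric vector of branch rates summing exactly to `k_app` (the
#'   largest branch absorbs the floating-point rounding of the division).
#' @export
branch_rates <- function(k_app, fractions) {
  stopifnot(is.numeric(k_app), length(k_app) == 1, k_app > 0)
  if (any(fractions < 0)) stop("fractions must be nonnegative")
  tot <- sum(fractions)
  if (tot <= 0) stop("at least one fraction must be positive")
  k <- k_app * fractions / tot
  j <- which.max(k)
  k[j] <- k_app - sum(k[-j])
  k
}
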