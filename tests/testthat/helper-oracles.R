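# Independent oracles and random-scheme generators used across the tests.
#
# The eigen-decomposition solver is cross-checked against two established
# references: the matrix exponential (Matrix::expm, scaling-and-squaring)
# and stiff ODE integration (deSolve::lsoda).  Random schemes are drawn from
# two classes with provably real spectra: irreversible acyclic networks
# (triangular rate matrices) and fully reversible trees (symmetrizable by a
# detailed-balance similarity transform).

# concentrations via the matrix exponential: c(t) = expm(A t) c0
expm_evolution <- function(A, c0, times) {
  A <- unclass(A)
  out <- vapply(times, function(t)
    as.numeric(Matrix::expm(Matrix::Matrix(A * t)) %*% c0),
    numeric(nrow(A)))
  t(out)                                   # n_times x n_states
}

# concentrations via stiff ODE integration (lsoda)
ode_evolution <- function(A, c0, times, rtol = 1e-10, atol = 1e-13) {
  A <- unclass(A)
  deriv <- function(t, y, parms) list(as.numeric(A %*% y))
  out <- deSolve::lsoda(y = as.numeric(c0), times = c(0, times),
                        func = deriv, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  unname(out[-1, -1, drop = FALSE])        # drop t = 0 row and time column
}

# random irreversible acyclic scheme: transitions only from lower to higher
# state index (triangular rate matrix, real eigenvalues)
random_acyclic_scheme <- function(n_states, rate_range = c(1, 1e7)) {
  states <- sprintf("S%d", seq_len(n_states))
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n_states - 1)) {
    targets <- (i + 1):n_states
    pick <- targets[runif(length(targets)) < 0.6]
    # ensure an outgoing edge; index the vector so a length-1 `targets`
    # is not treated by sample() as 1:targets
    if (!length(pick)) pick <- targets[sample.int(length(targets), 1)]
    from <- c(from, rep(i, length(pick)))
    to <- c(to, pick)
  }
  rates <- exp(runif(length(from), log(rate_range[1]), log(rate_range[2])))
  kinetic_scheme(states,
                 data.frame(from = states[from], to = states[to],
                            rate = rates),
                 initial = setNames(1, states[1]))
}

# random reversible tree: a spanning tree with both directions on each edge
# (detailed-balance symmetrizable, hence real eigenvalues)
random_reversible_tree <- function(n_states, rate_range = c(1, 1e7)) {
  states <- sprintf("S%d", seq_len(n_states))
  parent <- vapply(2:n_states, function(i) sample(i - 1, 1), 1L)
  lr <- function(k) exp(runif(k, log(rate_range[1]), log(rate_range[2])))
  tr <- data.frame(
    from = c(states[parent], states[2:n_states]),
    to   = c(states[2:n_states], states[parent]),
    rate = lr(2 * (n_states - 1)))
  c0 <- runif(n_states)
  kinetic_scheme(states, tr, initial = setNames(c0 / sum(c0), states))
}

# eigen-solve a scheme, silencing benign near-degeneracy warnings that
# random draws occasionally produce
solve_scheme <- function(scheme) {
  suppressWarnings(eigen_solve(build_kinetic_matrix(scheme)))
}

# a short log-spaced grid covering the dynamics of rates in [1, 1e7]
oracle_times <- function(n = 25) exp(seq(log(1e-8), log(2), length.out = n))
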