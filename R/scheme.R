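#' First-order kinetic scheme
#'
#' A labelled set of states connected by first-order transitions.  States
#' follow the retinal-protein convention: K (early red-shifted), L (blue
#' shifted), M (deprotonated Schiff base), N, O (late red-shifted, open
#' channel where flagged conductive), R (recovered).  Multiple states may
#' share one absorption spectrum (isospectral states).
#'
#' @param states character vector of state labels, order defines the rate
#'   matrix ordering.
#' @param transitions data frame with columns `from`, `to`, `rate` (s^-1,
#'   all > 0); or a list of `list(from=, to=, rate=)`.
#' @param conductive named logical (or character vector of conductive state
#'   labels); defaults to none.
#' @param initial named numeric of initial populations (fractions); states
#'   not named start at 0.  Populations must be nonnegative.
#' @return object of class `"kinetic_scheme"`.
#' @export
kinetic_scheme <- function(states, transitions, conductive = character(0),
                           initial) {
  stopifnot(is.character(states), length(states) >= 1,
            !anyDuplicated(states))
  if (is.list(transitions) && !is.data.frame(transitions)) {
    transitions <- do.call(rbind, lapply(transitions, function(tr)
      data.frame(from = tr$from, to = tr$to, rate = tr$rate)))
  }
  if (is.null(transitions) || nrow(transitions) == 0) {
    transitions <- data.frame(from = character(0), to = character(0),
                              rate = numeric(0))
  }
  stopifnot(all(c("from", "to", "rate") %in% names(transitions)))
  bad <- setdiff(unique(c(transitions$from, transitions$to)), states)
  if (length(bad)) {
    stop("transition references unknown state(s): ", paste(bad, collapse = ", "))
  }
  if (any(!is.finite(transitions$rate)) || any(transitions$rate <= 0)) {
    stop("all transition rates must be positive and finite")
  }
  if (is.character(conductive)) {
    conductive <- setNames(states %in% conductive, states)
  } else {
    flags <- setNames(rep(FALSE, length(states)), states)
    flags[names(conductive)] <- as.logical(conductive)
    conductive <- flags
  }
  c0 <- setNames(rep(0, length(states)), states)
  stopifnot(!is.null(names(initial)), all(names(initial) %in% states))
  if (any(initial < 0)) stop("initial populations must be nonnegative")
  c0[names(initial)] <- as.numeric(initial)
  structure(
    list(states = states,
         transitions = transitions[, c("from", "to", "rate")],
         conductive = conductive, initial = c0),
    class = "kinetic_scheme"
  )
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat(sprintf("<kinetic_scheme> %d states, %d transitions\n",
              length(x$states), nrow(x$transitions)))
  cond <- names(x$conductive)[x$conductive]
  cat("  states:", paste(x$states, collapse = ", "),
      if (length(cond)) sprintf("(conductive: %s)", paste(cond, collapse = ", "))
      else "", "\n")
  for (i in seq_len(nrow(x$transitions))) {
    tr <- x$transitions[i, ]
    cat(sprintf("  %s -> %s  %.4g s^-1\n", tr$from, tr$to, tr$rate))
  }
  invisible(x)
}

#' Merge parallel cycles into one scheme
#'
#' Parallel photocycles evolve independently; stacking them into one scheme
#' gives a block-diagonal rate matrix whose eigen-solution is the union of
#' the per-cycle solutions (shared rates become degenerate eigenvalues).
#'
#' @param ... `kinetic_scheme` objects with disjoint state labels.
#' @return a single `kinetic_scheme`.
#' @export
combine_schemes <- function(...) {
  schemes <- list(...)
  if (length(schemes) == 1 && is.list(schemes[[1]]) &&
      !inherits(schemes[[1]], "kinetic_scheme")) schemes <- schemes[[1]]
  stopifnot(all(vapply(schemes, inherits, TRUE, "kinetic_scheme")))
  states <- unlist(lapply(schemes, `[[`, "states"))
  if (anyDuplicated(states)) stop("parallel cycles must have disjoint state labels")
  transitions <- do.call(rbind, lapply(schemes, `[[`, "transitions"))
  conductive <- unlist(lapply(schemes, `[[`, "conductive"))
  initial <- unlist(lapply(schemes, `[[`, "initial"))
  kinetic_scheme(states, transitions, conductive, initial)
}

#' Serialize / deserialize a kinetic scheme as JSON
#'
#' Rates are written with 17 significant digits, which round-trips IEEE
#' doubles exactly.
#'
#' @param scheme a [kinetic_scheme()].
#' @param path file path; for `scheme_from_json` the file to read.
#' @return `scheme_to_json` returns `path` invisibly; `scheme_from_json`
#'   returns the reconstructed scheme.
#' @export
scheme_to_json <- function(scheme, path) {
  obj <- list(
    states = scheme$states,
    transitions = lapply(seq_len(nrow(scheme$transitions)), function(i)
      list(from = scheme$transitions$from[i],
           to = scheme$transitions$to[i],
           rate = scheme$transitions$rate[i])),
    conductive = scheme$states[scheme$conductive],
    initial = as.list(scheme$initial[scheme$initial > 0])
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname scheme_to_json
#' @export
scheme_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  transitions <- do.call(rbind, lapply(obj$transitions, function(tr)
    data.frame(from = tr$from, to = tr$to, rate = tr$rate)))
  kinetic_scheme(unlist(obj$states), transitions,
                 conductive = as.character(unlist(obj$conductive)),
                 initial = unlist(obj$initial))
}
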