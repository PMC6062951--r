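#' Complexes eligible for reduction
#'
#' A complex may be reduced only if it contains none of the important
#' compounds, so that the trajectories used for model comparison are never
#' themselves eliminated.
#'
#' @param model a [network_model()].
#' @return Integer vector of eligible complex indices, ascending.
#' @export
eligible_complexes <- function(model) {
  hit <- colSums(model$Z[model$important, , drop = FALSE] != 0) > 0
  unname(which(!hit))
}

#' Define one candidate reduction
#'
#' @param reduced integer vector of complex indices to eliminate (possibly
#'   empty; the empty set is the full, unreduced model).
#' @param eligible the ordered eligible set of the model, from
#'   [eligible_complexes()].
#' @return An object of class `reduction_spec`.
#' @export
reduction_spec <- function(reduced, eligible) {
  reduced <- sort(unique(as.integer(reduced)))
  if (!all(reduced %in% eligible)) {
    stop("reduction includes complexes outside the eligible set", call. = FALSE)
  }
  structure(
    list(reduced = reduced, eligible = sort(unique(as.integer(eligible))),
         size = length(reduced)),
    class = "reduction_spec"
  )
}

#' Bitmask label of a reduction
#'
#' One character per eligible complex, in ascending eligible order; `1`
#' marks a reduced complex.  `"00...0"` is the full model.  Bitmasks key
#' all output tables.
#'
#' @param spec a [reduction_spec()].
#' @return A single string.
#' @export
bitmask <- function(spec) {
  paste(as.integer(spec$eligible %in% spec$reduced), collapse = "")
}

#' @export
print.reduction_spec <- function(x, ...) {
  cat("<reduction_spec> [", bitmask(x), "] reducing ",
      if (x$size == 0) "nothing (full model)" else
        paste(x$reduced, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Enumerate every possible reduction
#'
#' All `2^c` subsets of the eligible set, ordered by subset size and then
#' lexicographically, starting with the empty set (the full model).
#'
#' @param eligible integer vector of eligible complex indices.
#' @param cap refuse enumeration beyond this many eligible complexes;
#'   two-stage prefiltering (see [prefilter_reductions()]) is the intended
#'   route for larger eligible sets.
#' @return List of [reduction_spec()] objects of length `2^c`.
#' @export
enumerate_reductions <- function(eligible, cap = 16) {
  eligible <- sort(unique(as.integer(eligible)))
  c_n <- length(eligible)
  if (c_n > cap) {
    stop("2^", c_n, " reductions exceed the enumeration cap (", cap,
         "); prefilter with a pilot run instead", call. = FALSE)
  }
  specs <- list(reduction_spec(integer(0), eligible))
  for (s in seq_len(c_n)) {
    combos <- utils::combn(eligible, s, simplify = FALSE)
    specs <- c(specs, lapply(combos, reduction_spec, eligible = eligible))
  }
  specs
}

#' Reduce a model by eliminating a set of complexes
#'
#' Builds the reduced model in which every complex in `spec` is removed
#' from the dynamics by imposing its quasi-steady-state balance: the
#' concentration of each eliminated compound is, at every instant, the
#' value that makes its net production rate zero given the current state of
#' the retained compounds.  This is the complex-elimination reduction for
#' reaction networks in the complex formalism; the eliminated
#' concentrations relax onto the retained ones and converge to the full
#' model's steady-state values as the system settles (the reduction is
#' anchored at the full model's steady state under the *same* parameter
#' set, which is also used to report the eliminated complex
#' concentrations).  The result is independent of the order in which
#' complexes are eliminated.
#'
#' Elimination is exact, via one linear solve per evaluation, when every
#' reduced complex consists of a single compound with coefficient one and
#' that compound appears in no retained complex — the structure of both
#' bundled network families.  Specs outside this class have no well-defined
#' elimination here and are rejected rather than silently approximated.
#'
#' @inheritParams simulate_model
#' @param spec a [reduction_spec()].
#' @param full_ss converged steady state of the full model under `params`
#'   (from [steady_state()]).
#' @return An object of class `reduced_model`.
#' @export
reduce_model <- function(model, params, spec, full_ss) {
  stopifnot(inherits(model, "network_model"), inherits(spec, "reduction_spec"))
  if (!all(spec$reduced %in% eligible_complexes(model))) {
    stop("spec reduces complexes that are not eligible for this model",
         call. = FALSE)
  }
  check_params(model, params)
  ss <- as.numeric(full_ss)

  n_cx <- ncol(model$Z)
  single <- colSums(model$Z[, spec$reduced, drop = FALSE] != 0) == 1 &
    colSums(model$Z[, spec$reduced, drop = FALSE]) == 1
  if (any(!single)) {
    stop("unsupported reduction: complex(es) ",
         paste(model$complex_names[spec$reduced[!single]], collapse = ", "),
         " are not single-compound, coefficient-one complexes", call. = FALSE)
  }
  membership <- model$Z != 0
  in_reduced <- rowSums(membership[, spec$reduced, drop = FALSE]) > 0
  in_kept <- rowSums(membership[, setdiff(seq_len(n_cx), spec$reduced),
                                drop = FALSE]) > 0
  if (any(in_reduced & in_kept)) {
    bad <- model$compound_names[in_reduced & in_kept]
    stop("unsupported reduction: compound(s) ", paste(bad, collapse = ", "),
         " belong to both reduced and retained complexes", call. = FALSE)
  }
  eliminated <- which(in_reduced)

  cc_ss <- complex_concentrations(model$Z, ss)
  structure(
    list(
      base = model,
      spec = spec,
      eliminated_compounds = eliminated,
      kept_compounds = setdiff(seq_along(model$compound_names), eliminated),
      ss_complex_values = stats::setNames(cc_ss[spec$reduced],
                                          model$complex_names[spec$reduced]),
      steady_state = stats::setNames(ss, model$compound_names)
    ),
    class = "reduced_model"
  )
}

#' @export
print.reduced_model <- function(x, ...) {
  cat("<reduced_model> [", bitmask(x$spec), "] of ", x$base$name, "\n", sep = "")
  if (x$spec$size > 0) {
    cat("  eliminated complexes: ",
        paste(names(x$ss_complex_values), collapse = ", "),
        " (quasi-steady-state)\n", sep = "")
  } else cat("  (empty spec: identical to the full model)\n")
  invisible(x)
}

# Quasi-steady-state solver for the eliminated compounds.  Within the
# supported class the net production of the eliminated block is affine in
# its own concentrations, rhs_F(x_F) = c + M x_F; c (and, with non-constant
# kinetic modifiers, M) is extracted numerically from the full rhs and the
# balance solved exactly.  `M_fixed` caches the mass-action case where M
# depends only on the rate constants.
qss_solver <- function(reduced, params) {
  base <- reduced$base
  F_ <- reduced$eliminated_compounds
  template <- as.numeric(reduced$steady_state)
  rhs_F <- function(x, xf) {
    x[F_] <- xf
    network_rhs_fast(base, params, x)[F_]
  }
  extract_M <- function(x) {
    c0 <- rhs_F(x, rep(0, length(F_)))
    M <- vapply(seq_along(F_), function(l) {
      rhs_F(x, as.numeric(seq_along(F_) == l)) - c0
    }, numeric(length(F_)))
    list(M = matrix(M, length(F_)), c0 = c0)
  }
  M_fixed <- if (is.null(base$kinetics)) extract_M(template)$M
  function(x) {
    if (is.null(M_fixed)) {
      lin <- extract_M(x)
      M <- lin$M
      c0 <- lin$c0
    } else {
      M <- M_fixed
      c0 <- rhs_F(x, rep(0, length(F_)))
    }
    xf <- tryCatch(solve(M, -c0), error = function(e) {
      stop("quasi-steady-state balance is singular for reduction [",
           bitmask(reduced$spec), "]", call. = FALSE)
    })
    pmax(as.numeric(xf), 0)
  }
}

# ODE right-hand side of the retained compounds: fill the eliminated block
# with its quasi-steady-state values, then read off the retained rates.
reduced_rhs_function <- function(reduced, params) {
  base <- reduced$base
  F_ <- reduced$eliminated_compounds
  K_ <- reduced$kept_compounds
  qss <- qss_solver(reduced, params)
  template <- as.numeric(reduced$steady_state)
  function(t, y, p) {
    x <- template
    x[K_] <- pmax(y, 0)
    x[F_] <- qss(x)
    list(network_rhs_fast(base, params, x)[K_])
  }
}

# Full state at one or more time points of a reduced trajectory: retained
# compounds from the integrator, eliminated compounds from the
# quasi-steady-state relation.
augment_reduced_states <- function(reduced, params, kept_states) {
  F_ <- reduced$eliminated_compounds
  K_ <- reduced$kept_compounds
  qss <- qss_solver(reduced, params)
  template <- as.numeric(reduced$steady_state)
  t(apply(kept_states, 1, function(yk) {
    x <- template
    x[K_] <- pmax(yk, 0)
    x[F_] <- qss(x)
    x
  }))
}

#' Greedy one-complex-at-a-time reduction
#'
#' The baseline iterative procedure: starting from the full model,
#' repeatedly eliminate the single eligible complex whose addition gives
#' the smallest symmetric error to the full model's trajectory, stopping
#' before the first step whose best achievable error exceeds the cut-off.
#' Ties are broken towards the lowest complex index.
#'
#' @inheritParams simulate_model
#' @param threshold non-negative symmetric-error cut-off.
#' @param horizon evaluation horizon `T`; `NULL` resolves it with
#'   [evaluation_horizon()].
#' @return Integer vector of eliminated complex indices, in reduction order
#'   (possibly empty), with the final symmetric error in attribute
#'   `"error"`.
#' @export
greedy_reduce <- function(model, params, threshold, horizon = NULL,
                          n_grid = 1000, rtol = 1e-8, atol = 1e-10) {
  stopifnot(threshold >= 0)
  ss <- steady_state(model, params, rtol = rtol, atol = atol)
  if (is.null(horizon)) {
    horizon <- evaluation_horizon(model, params, ss, rtol = rtol, atol = atol)
  }
  full_traj <- simulate_model(model, params, horizon, n_grid, rtol, atol)
  eligible <- eligible_complexes(model)
  chosen <- integer(0)
  err <- 0
  repeat {
    remaining <- setdiff(eligible, chosen)
    if (length(remaining) == 0) break
    errors <- vapply(remaining, function(e) {
      spec <- reduction_spec(c(chosen, e), eligible)
      red <- reduce_model(model, params, spec, ss)
      traj <- simulate_model(red, params, horizon, n_grid, rtol, atol)
      symmetric_error(traj, full_traj, model$important)
    }, 0)
    best <- which.min(errors)                      # which.min takes first tie
    if (errors[best] > threshold) break
    chosen <- c(chosen, remaining[best])
    err <- errors[best]
  }
  attr(chosen, "error") <- err
  chosen
}
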