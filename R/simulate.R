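#' Integrate a model over a time horizon
#'
#' Solves the network ODE from the parameter set's initial values with an
#' adaptive, stiffness-switching integrator (`deSolve::lsoda`) and reports the
#' solution on a uniform grid.  Works for both full models and clamped
#' reduced models (see [reduce_model()]); for a reduced model the frozen
#' compounds start, and stay, at their full-model steady-state values.
#'
#' @param model a [network_model()] or a `reduced_model` from
#'   [reduce_model()].
#' @param params a [parameter_set()].
#' @param horizon positive end time `T` of the evaluation interval.
#' @param n_grid number of uniform grid points on `[0, T]` (at least 2).
#' @param rtol,atol relative and absolute solver tolerances.
#'
#' @return A tibble with a `time` column and one column per compound, of
#'   class `redeval_trajectory`, carrying the horizon as an attribute.
#' @export
simulate_model <- function(model, params, horizon, n_grid = 1000,
                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(horizon > 0, n_grid >= 2)
  times <- seq(0, horizon, length.out = n_grid)
  out <- integrate_states(model, params, times, rtol, atol)
  base <- if (inherits(model, "reduced_model")) model$base else model
  traj <- tibble::as_tibble(as.data.frame(out))
  names(traj) <- c("time", base$compound_names)
  attr(traj, "horizon") <- horizon
  class(traj) <- c("redeval_trajectory", class(traj))
  traj
}

# Shared lsoda call used by simulate_model() and steady_state(); returns the
# deSolve matrix and raises a simulation error naming the parameter set if
# integration degenerates.
integrate_states <- function(model, params, times, rtol, atol) {
  if (inherits(model, "reduced_model") && model$spec$size == 0) {
    model <- model$base                            # empty spec: full model
  }
  reduced <- inherits(model, "reduced_model")
  if (reduced) {
    base <- model$base
    check_params(base, params)
    x0 <- unname(params$x0)[model$kept_compounds]
    rhs <- reduced_rhs_function(model, params)
  } else {
    base <- model
    check_params(base, params)
    x0 <- unname(params$x0)
    rhs <- function(t, y, p) list(network_rhs_fast(base, params, y))
  }
  out <- tryCatch(
    deSolve::lsoda(y = x0, times = times, func = rhs, parms = NULL,
                   rtol = rtol, atol = atol),
    error = function(e) e, warning = function(w) w
  )
  id <- attr(params, "set_id") %||% "<reference>"
  if (inherits(out, "condition")) {
    stop("integration failed for parameter set ", id, ": ",
         conditionMessage(out), call. = FALSE)
  }
  if (nrow(out) < length(times) || anyNA(out) || any(!is.finite(out))) {
    stop("integration did not reach the horizon for parameter set ", id,
         call. = FALSE)
  }
  if (reduced) {
    states <- augment_reduced_states(model, params,
                                     out[, -1, drop = FALSE])
    out <- cbind(out[, 1], states)
  }
  out
}

# rhs without the per-call validation overhead; lsoda may probe slightly
# negative states, which are clipped at zero before the power products.
network_rhs_fast <- function(model, params, state) {
  state <- pmax(state, 0)
  cc <- complex_concentrations(model$Z, state)
  k <- unname(params$params[model$rate_params])
  v <- k * cc[model$substrate]
  if (!is.null(model$kinetics)) {
    d <- vapply(model$kinetics, function(f) if (is.null(f)) 1 else f(state), 0)
    v <- v * d
  }
  vb <- boundary_flux(model, params, cc)
  drop(model$Z %*% (model$B %*% v + vb))
}

#' Locate the steady state of a model
#'
#' Integrates the system in doubling time windows until the max-norm of the
#' right-hand side falls below `tol * (1 + max(state))`, the criterion for a
#' numerically converged steady state.  The method assumes the model is
#' asymptotically stable; if the hard horizon cap is hit first an error is
#' raised, since the reduction procedure is undefined without a steady state.
#'
#' @inheritParams simulate_model
#' @param tol relative steady-state tolerance on the right-hand side.
#' @param t_start first integration window length (doubled each round).
#' @param t_cap hard cap on total integration time.
#'
#' @return Named numeric steady-state concentration vector, with the total
#'   integration time in attribute `"t_converged"`.
#' @export
steady_state <- function(model, params, tol = 1e-8,
                         t_start = 50, t_cap = 1e6,
                         rtol = 1e-8, atol = 1e-10) {
  check_params(model, params)
  state <- unname(params$x0)
  t_total <- 0
  window <- t_start
  repeat {
    out <- integrate_states(
      model,
      restate_params(params, state),
      times = c(0, window / 2, window), rtol = rtol, atol = atol
    )
    state <- pmax(out[nrow(out), -1], 0)
    t_total <- t_total + window
    resid <- max(abs(network_rhs_fast(model, params, state)))
    if (resid < tol * (1 + max(state))) break
    if (t_total >= t_cap) {
      stop("no steady state within a horizon of ", t_cap,
           " time units (residual ", signif(resid, 3), ")", call. = FALSE)
    }
    window <- window * 2
  }
  names(state) <- model$compound_names
  attr(state, "t_converged") <- t_total
  state
}

restate_params <- function(params, state) {
  p <- params
  p$x0 <- stats::setNames(as.numeric(state), names(params$x0))
  p
}

#' Choose the evaluation horizon T
#'
#' Picks the time at which the full model's trajectory has come within a
#' given relative distance of its steady state (1% by default) and stays
#' there.  All models of one analysis share this `T` so that their error
#' integrals are comparable: a shorter horizon misses part of the transient,
#' a much longer one reduces the error to a difference of steady states.
#'
#' @inheritParams simulate_model
#' @param ss optional precomputed steady state (otherwise [steady_state()]
#'   is called).
#' @param frac relative closeness to the steady state defining "settled".
#' @param n_search number of grid points used to bracket the settling time.
#' @return Positive scalar horizon.
#' @export
evaluation_horizon <- function(model, params, ss = NULL, frac = 0.01,
                               n_search = 2000, rtol = 1e-8, atol = 1e-10) {
  if (is.null(ss)) ss <- steady_state(model, params, rtol = rtol, atol = atol)
  t_max <- attr(ss, "t_converged") %||% 100
  times <- seq(0, t_max, length.out = n_search)
  out <- integrate_states(model, params, times, rtol, atol)
  states <- out[, -1, drop = FALSE]
  scale <- pmax(abs(as.numeric(ss)), 1e-12)
  dev <- sweep(abs(sweep(states, 2, as.numeric(ss))), 2, scale, "/")
  worst <- apply(dev, 1, max)
  beyond <- which(worst > frac)
  if (length(beyond) == 0) return(times[2])
  idx <- max(beyond) + 1
  if (idx > length(times)) {
    stop("trajectory not settled within the steady-state search horizon",
         call. = FALSE)
  }
  times[idx]
}

#' Write a trajectory to delimited text
#'
#' One row per time point; first column is time, remaining columns are the
#' compound concentrations, named in the header.
#'
#' @param traj a trajectory tibble from [simulate_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  write_full_precision(as.data.frame(traj), path)
  invisible(path)
}

# Tab-delimited writer that preserves doubles exactly (17 significant
# digits survive the text round trip).
write_full_precision <- function(df, path) {
  fmt <- vapply(df, is.numeric, TRUE)
  out <- df
  out[fmt] <- lapply(df[fmt], function(x) sprintf("%.17g", x))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
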