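#' Construct a biochemical network model in the complex formalism
#'
#' A network is described by the stoichiometry of its complexes (`Z`), a
#' linkage matrix (`B`) pairing each internal reaction with a substrate and a
#' product complex, a table of boundary fluxes, and the set of *important*
#' compounds whose trajectories define all model comparisons.  The dynamics
#' are \eqn{\dot x = Z B v(x) + Z v_b(x)} with internal fluxes
#' \eqn{v_j(x) = k_j d_j(x) \prod_i x_i^{Z_{i,s(j)}}}, i.e. mass-action in the
#' substrate complex \eqn{s(j)} times an optional kinetic modifier
#' \eqn{d_j}.
#'
#' @param Z numeric matrix, compounds by complexes; non-negative integer
#'   stoichiometric coefficients, no all-zero column.
#' @param B numeric matrix, complexes by reactions; each column has exactly
#'   one `-1` (substrate complex) and one `+1` (product complex).
#' @param boundary data frame with columns `complex` (index), `type`
#'   (`"in"` for a constant inflow, `"out"` for a first-order outflow) and
#'   `param` (name of the rate parameter).  May have zero rows.
#' @param important character or integer vector of important compounds
#'   (the set whose concentrations are compared across models); complexes
#'   containing any of them are never eligible for reduction.
#' @param rate_params character vector, one kinetic parameter name per
#'   reaction (defaults to `k1 ... kR`).
#' @param kinetics optional list of kinetic-modifier functions
#'   `function(state) -> scalar`, one per reaction; `NULL` entries (and a
#'   `NULL` list) mean mass action, \eqn{d_j \equiv 1}.
#' @param compound_names,complex_names,reaction_names optional labels.
#' @param name optional model name used in file output.
#'
#' @return An object of class `network_model`.
#' @seealso [build_simple_example()], [read_network()], [eligible_complexes()]
#' @export
network_model <- function(Z, B, boundary, important,
                          rate_params = NULL, kinetics = NULL,
                          compound_names = NULL, complex_names = NULL,
                          reaction_names = NULL, name = "network") {
  Z <- as.matrix(Z)
  B <- as.matrix(B)
  n_comp <- nrow(Z)
  n_cx <- ncol(Z)
  n_rxn <- ncol(B)
  if (nrow(B) != n_cx) {
    stop("`B` must have one row per complex (column of `Z`)", call. = FALSE)
  }
  if (any(Z < 0) || any(Z != round(Z))) {
    stop("`Z` must contain non-negative integer stoichiometries", call. = FALSE)
  }
  if (any(colSums(Z) == 0)) {
    stop("`Z` must not contain an all-zero complex column", call. = FALSE)
  }
  ok_col <- function(b) sum(b == -1) == 1 && sum(b == 1) == 1 && all(b %in% c(-1, 0, 1))
  if (!all(apply(B, 2, ok_col))) {
    stop("every column of `B` must have exactly one -1 and one +1", call. = FALSE)
  }

  compound_names <- compound_names %||% rownames(Z) %||% paste0("X", seq_len(n_comp))
  complex_names <- complex_names %||% colnames(Z) %||% paste0("C", seq_len(n_cx))
  reaction_names <- reaction_names %||% paste0("R", seq_len(n_rxn))
  rate_params <- rate_params %||% paste0("k", seq_len(n_rxn))
  stopifnot(length(rate_params) == n_rxn)
  dimnames(Z) <- list(compound_names, complex_names)

  if (is.character(important)) important <- match(important, compound_names)
  important <- sort(unique(as.integer(important)))
  if (length(important) == 0 || anyNA(important) ||
      any(important < 1) || any(important > n_comp)) {
    stop("`important` must be a non-empty subset of the compounds", call. = FALSE)
  }

  boundary <- tibble::as_tibble(boundary)
  if (nrow(boundary) > 0) {
    stopifnot(all(c("complex", "type", "param") %in% names(boundary)))
    if (!all(boundary$type %in% c("in", "out"))) {
      stop("boundary `type` must be \"in\" or \"out\"", call. = FALSE)
    }
    boundary$complex <- as.integer(boundary$complex)
    stopifnot(all(boundary$complex >= 1), all(boundary$complex <= n_cx))
  }

  if (!is.null(kinetics)) stopifnot(length(kinetics) == n_rxn)

  structure(
    list(
      Z = Z, B = B,
      substrate = apply(B, 2, function(b) which(b == -1)),
      product = apply(B, 2, function(b) which(b == 1)),
      boundary = boundary,
      important = important,
      rate_params = rate_params,
      kinetics = kinetics,
      compound_names = compound_names,
      complex_names = complex_names,
      reaction_names = reaction_names,
      name = name
    ),
    class = "network_model"
  )
}

#' @export
print.network_model <- function(x, ...) {
  cat("<network_model> ", x$name, "\n", sep = "")
  cat("  compounds: ", length(x$compound_names), " (",
      paste(x$compound_names, collapse = ", "), ")\n", sep = "")
  cat("  complexes: ", length(x$complex_names),
      "   reactions: ", length(x$reaction_names),
      "   boundary fluxes: ", nrow(x$boundary), "\n", sep = "")
  cat("  important set: ",
      paste(x$compound_names[x$important], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Bundle reference parameter values and initial values
#'
#' @param params named numeric vector of all rate parameters (kinetic
#'   proportionality constants and boundary rates), all non-negative.
#' @param x0 named numeric vector of non-negative initial concentrations,
#'   one per compound.
#'
#' @return An object of class `parameter_set`.
#' @export
parameter_set <- function(params, x0) {
  params <- unlist(params)
  x0 <- unlist(x0)
  if (any(params < 0) || any(x0 < 0)) {
    stop("parameters and initial values must be non-negative", call. = FALSE)
  }
  if (is.null(names(params)) || is.null(names(x0))) {
    stop("`params` and `x0` must be named", call. = FALSE)
  }
  structure(list(params = params, x0 = x0), class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set> ", length(x$params), " parameters, ",
      length(x$x0), " initial values\n", sep = "")
  print(x$params)
  invisible(x)
}

check_state <- function(model, state) {
  if (length(state) != length(model$compound_names)) {
    stop("state length does not match the number of compounds", call. = FALSE)
  }
  if (any(state < 0)) {
    stop("negative concentration in state", call. = FALSE)
  }
  invisible(state)
}

check_params <- function(model, params) {
  need <- unique(c(model$rate_params, model$boundary$param))
  missing <- setdiff(need, names(params$params))
  if (length(missing) > 0) {
    stop("parameter set is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(params$x0) != length(model$compound_names)) {
    stop("initial values do not match the number of compounds", call. = FALSE)
  }
  invisible(params)
}

# Complex concentrations exp(Z^T Ln x) evaluated as products of powers, so a
# zero concentration gives a zero complex term (0^0 == 1 covers absentees)
# instead of a log-of-zero failure.
complex_concentrations <- function(Z, state) {
  apply(Z, 2, function(z) prod(state^z))
}

#' Evaluate the internal reaction fluxes
#'
#' Computes \eqn{v_j = k_j d_j(x) \prod_i x_i^{Z_{i,s(j)}}} for every internal
#' reaction at the given state.
#'
#' @param model a [network_model()].
#' @param params a [parameter_set()].
#' @param state non-negative numeric concentration vector.
#' @return Numeric vector of fluxes, one per reaction.
#' @export
evaluate_fluxes <- function(model, params, state) {
  check_state(model, state)
  check_params(model, params)
  cc <- complex_concentrations(model$Z, state)
  k <- unname(params$params[model$rate_params])
  v <- k * cc[model$substrate]
  if (!is.null(model$kinetics)) {
    d <- vapply(model$kinetics, function(f) if (is.null(f)) 1 else f(state), 0)
    v <- v * d
  }
  v
}

boundary_flux <- function(model, params, cc) {
  vb <- numeric(ncol(model$Z))
  bd <- model$boundary
  if (nrow(bd) > 0) {
    rates <- unname(params$params[bd$param])
    for (r in seq_len(nrow(bd))) {
      j <- bd$complex[r]
      vb[j] <- vb[j] + if (bd$type[r] == "in") rates[r] else -rates[r] * cc[j]
    }
  }
  vb
}

#' Evaluate the right-hand side of the network ODE
#'
#' Returns \eqn{Z B v(x) + Z v_b(x)}: the net production rate of every
#' compound from internal and boundary fluxes.
#'
#' @inheritParams evaluate_fluxes
#' @return Numeric derivative vector, one entry per compound.
#' @export
network_rhs <- function(model, params, state) {
  check_state(model, state)
  check_params(model, params)
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

#' The four-compound reference network
#'
#' Builds the bundled example: a diamond-shaped mass-action network in which
#' compound 1 feeds two parallel intermediates (2 and 3) that both drain into
#' compound 4; material enters at compound 1 at constant rate `k5` and leaves
#' from compound 4 with first-order rate `k6`.  The important set is
#' compounds 1 and 4, so the two intermediates are the reduction candidates.
#'
#' @return A list with components `model` (a [network_model()]) and
#'   `reference` (the reference [parameter_set()]).
#' @examples
#' ex <- build_simple_example()
#' network_rhs(ex$model, ex$reference, ex$reference$x0)
#' @export
build_simple_example <- function() {
  Z <- diag(4)
  B <- cbind(
    c(-1, 1, 0, 0),
    c(-1, 0, 1, 0),
    c(0, -1, 0, 1),
    c(0, 0, -1, 1)
  )
  model <- network_model(
    Z = Z, B = B,
    boundary = tibble::tibble(
      complex = c(1L, 4L), type = c("in", "out"), param = c("k5", "k6")
    ),
    important = c(1L, 4L),
    compound_names = paste0("X", 1:4),
    name = "simple_example"
  )
  reference <- parameter_set(
    params = c(k1 = 0.44, k2 = 0.03, k3 = 0.55, k4 = 0.44, k5 = 0.42, k6 = 0.33),
    x0 = c(X1 = 0.4, X2 = 0.0, X3 = 0.5, X4 = 0.4)
  )
  list(model = model, reference = reference)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
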