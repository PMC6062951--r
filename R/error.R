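#' Time-averaged relative trajectory error
#'
#' The (one-sided) error integral between two trajectories over the
#' important compounds:
#' \deqn{I_T(x_r, x_f) = \frac{1}{T\,n(M_I)} \sum_{i \in M_I}
#'   \int_0^T \left|1 - \frac{x_{ir}(t)}{x_{if}(t)}\right| dt,}
#' evaluated by composite trapezoidal quadrature on the trajectories' shared
#' uniform grid.  The denominator is floored at `epsilon` so a zero
#' reference concentration (possible at `t = 0`) cannot divide out.
#'
#' @param reduced,reference trajectory tibbles from [simulate_model()] on
#'   identical time grids (`reference` supplies the denominator).
#' @param important integer indices or names of the important compounds.
#' @param epsilon floor for the denominator concentration.
#' @return Non-negative scalar.
#' @export
error_integral <- function(reduced, reference, important, epsilon = 1e-12) {
  g <- check_shared_grid(reduced, reference)
  a <- trajectory_states(reduced, important)
  b <- trajectory_states(reference, important)
  w <- trapezoid_weights(g$time)
  sum(w * abs(1 - a / pmax(b, epsilon))) / (g$horizon * ncol(a))
}

#' Symmetric trajectory error
#'
#' The dissimilarity used throughout the clustering:
#' \eqn{E_T(x_1, x_2) = (I_T(x_1, x_2) + I_T(x_2, x_1)) / 2}.  It is defined
#' for any two models — reduced or full, same parameters or not — as long
#' as they share the important set and time grid.
#'
#' @inheritParams error_integral
#' @param traj_a,traj_b trajectory tibbles on identical grids.
#' @return Non-negative scalar, symmetric in its two trajectories.
#' @export
symmetric_error <- function(traj_a, traj_b, important, epsilon = 1e-12) {
  (error_integral(traj_a, traj_b, important, epsilon) +
     error_integral(traj_b, traj_a, important, epsilon)) / 2
}

check_shared_grid <- function(a, b) {
  ta <- a$time
  tb <- b$time
  if (length(ta) != length(tb) || any(ta != tb)) {
    stop("trajectories are not on the same time grid", call. = FALSE)
  }
  list(time = ta, horizon = ta[length(ta)])
}

trajectory_states <- function(traj, important) {
  m <- as.matrix(traj[, -1, drop = FALSE])
  if (is.character(important)) important <- match(important, colnames(m))
  m[, important, drop = FALSE]
}

trapezoid_weights <- function(time) {
  h <- diff(time)
  w <- numeric(length(time))
  w[-length(w)] <- h / 2
  w[-1] <- w[-1] + h / 2
  w
}

#' All-pairs symmetric-error matrix
#'
#' Computes \eqn{E_T} between every pair of a labelled collection of
#' trajectories — typically the `n_sets * 2^c` models of one analysis.  The
#' result is symmetric with a zero diagonal and independent of evaluation
#' order.  Trajectories containing non-finite values are excluded with a
#' warning; their labels are recorded in attribute `"excluded"`.
#'
#' @param trajectories named list of trajectory tibbles on a shared grid;
#'   names are the `"<set id>|<bitmask>"` labels used downstream.
#' @inheritParams error_integral
#' @return A square numeric matrix of class `dissimilarity_matrix` with the
#'   labels as dimnames.
#' @export
dissimilarity_matrix <- function(trajectories, important, epsilon = 1e-12) {
  stopifnot(length(trajectories) >= 1, !is.null(names(trajectories)))
  time <- trajectories[[1]]$time
  keep <- vapply(trajectories, function(tr) all(is.finite(as.matrix(tr))), TRUE)
  excluded <- names(trajectories)[!keep]
  if (length(excluded) > 0) {
    warning("excluding ", length(excluded),
            " trajectories with non-finite values: ",
            paste(utils::head(excluded, 5), collapse = ", "),
            if (length(excluded) > 5) ", ..." else "")
    trajectories <- trajectories[keep]
  }
  for (tr in trajectories) check_shared_grid(trajectories[[1]], tr)

  V <- vapply(
    trajectories,
    function(tr) as.numeric(trajectory_states(tr, important)),
    numeric(length(time) * length(important))
  )
  D <- pairwise_errors(V, time, length(important), epsilon)
  dimnames(D) <- list(names(trajectories), names(trajectories))
  attr(D, "excluded") <- excluded
  class(D) <- c("dissimilarity_matrix", class(D))
  D
}

# V holds one model per column (important-compound states stacked).  One
# pass per denominator column vectorizes the whole row of one-sided
# integrals; symmetrizing afterwards gives E_T for every unordered pair.
pairwise_errors <- function(V, time, n_important, epsilon) {
  n <- ncol(V)
  horizon <- time[length(time)]
  w <- rep(trapezoid_weights(time), n_important) / (horizon * n_important)
  I <- matrix(0, n, n)
  for (b in seq_len(n)) {
    denom <- pmax(V[, b], epsilon)
    I[, b] <- crossprod(abs(1 - V / denom), w)
  }
  E <- (I + t(I)) / 2
  diag(E) <- 0
  E
}

#' Write / read a dissimilarity matrix
#'
#' Tab-delimited square matrix with the labels as header and first column;
#' values round-trip at full double precision.
#'
#' @param D a `dissimilarity_matrix`.
#' @param path file path.
#' @return `path` (writer, invisibly) or the matrix (reader).
#' @export
write_dissimilarity <- function(D, path) {
  df <- data.frame(label = rownames(D), unclass(D), check.names = FALSE)
  write_full_precision(df, path)
  invisible(path)
}

#' @rdname write_dissimilarity
#' @export
read_dissimilarity <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  D <- as.matrix(df[, -1, drop = FALSE])
  rownames(D) <- df$label
  class(D) <- c("dissimilarity_matrix", class(D))
  D
}
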