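# Independent oracles used across the suite.  None of them share code with
# the implementation paths they check.

# Closed-form solution of an affine linear system xdot = A x + b via the
# matrix exponential of the augmented system; exact for linear mass-action
# networks.  A and b are extracted by probing the rhs at unit states, which
# is exact when the rhs is affine.
affine_from_rhs <- function(rhs, n) {
  b <- rhs(rep(0, n))
  A <- vapply(seq_len(n), function(i) rhs(as.numeric(seq_len(n) == i)) - b,
              numeric(n))
  list(A = matrix(A, n), b = b)
}

matexp_trajectory <- function(rhs, x0, times) {
  n <- length(x0)
  af <- affine_from_rhs(rhs, n)
  Aug <- rbind(cbind(af$A, af$b), 0)
  t(vapply(times, function(t) {
    y <- as.numeric(Matrix::expm(Aug * t) %*% c(x0, 1))
    y[seq_len(n)]
  }, numeric(n)))
}

matexp_network_trajectory <- function(model, params, times) {
  rhs <- function(x) network_rhs(model, params, x)
  matexp_trajectory(rhs, unname(params$x0), times)
}

# O(N^3) single-linkage reference: clusters as index sets, repeatedly merge
# the pair with the smallest minimum cross distance.
brute_single_linkage_heights <- function(D) {
  D <- as.matrix(D)
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        d <- min(D[clusters[[i]], clusters[[j]]])
        if (d < best[1]) best <- c(d, j, i)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# Direct ECDF sup-difference two-sample KS statistic.
ecdf_ks <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  Fa <- vapply(grid, function(g) mean(a <= g), 0)
  Fb <- vapply(grid, function(g) mean(b <= g), 0)
  max(abs(Fa - Fb))
}

simple_example_fixture <- function() build_simple_example()

# Reference trajectory pair for error-metric tests: full model and the
# doubly-reduced model of the bundled example on a shared grid.
simple_reduction_pair <- function(n_grid = 1000, horizon = NULL) {
  ex <- simple_example_fixture()
  ss <- steady_state(ex$model, ex$reference)
  if (is.null(horizon)) horizon <- evaluation_horizon(ex$model, ex$reference, ss)
  spec <- reduction_spec(c(2, 3), eligible_complexes(ex$model))
  red <- reduce_model(ex$model, ex$reference, spec, ss)
  list(
    full = simulate_model(ex$model, ex$reference, horizon, n_grid),
    reduced = simulate_model(red, ex$reference, horizon, n_grid),
    model = ex$model, reference = ex$reference, ss = ss, horizon = horizon
  )
}

# Synthetic trajectory tibble on a given grid (for metric unit tests).
toy_trajectory <- function(time, states) {
  tr <- tibble::as_tibble(as.data.frame(cbind(time, states)))
  names(tr) <- c("time", paste0("X", seq_len(ncol(states))))
  attr(tr, "horizon") <- time[length(time)]
  class(tr) <- c("redeval_trajectory", class(tr))
  tr
}
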