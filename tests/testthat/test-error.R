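test_that("identical trajectories have zero error", {
  time <- seq(0, 10, length.out = 101)
  x <- cbind(1 + time, 2 + sin(time))
  tr <- toy_trajectory(time, x)
  expect_identical(error_integral(tr, tr, 1:2), 0)
  expect_identical(symmetric_error(tr, tr, 1:2), 0)
})

test_that("a uniform factor-of-two deviation gives unit error integral", {
  time <- seq(0, 7, length.out = 201)
  base <- cbind(0.5 + time / 10, exp(-time) + 0.1)
  a <- toy_trajectory(time, 2 * base)
  b <- toy_trajectory(time, base)
  # integrand is the constant 1, and the T * n(M_I) normalization cancels
  expect_equal(error_integral(a, b, 1:2), 1, tolerance = 1e-12)
  # reverse direction: |1 - 1/2| = 1/2
  expect_equal(error_integral(b, a, 1:2), 0.5, tolerance = 1e-12)
  expect_equal(symmetric_error(a, b, 1:2), 0.75, tolerance = 1e-12)
  expect_identical(symmetric_error(a, b, 1:2), symmetric_error(b, a, 1:2))
})

test_that("the error is invariant to a common rescaling of both models", {
  time <- seq(0, 5, length.out = 101)
  xa <- cbind(1 + sin(time)^2, 2 + time / 5)
  xb <- cbind(1.2 + cos(time)^2, 1.5 + time / 7)
  a <- toy_trajectory(time, xa)
  b <- toy_trajectory(time, xb)
  a2 <- toy_trajectory(time, 3.7 * xa)
  b2 <- toy_trajectory(time, 3.7 * xb)
  expect_equal(symmetric_error(a2, b2, 1:2), symmetric_error(a, b, 1:2),
               tolerance = 1e-12)
})

test_that("trajectories on different grids are rejected", {
  a <- toy_trajectory(seq(0, 1, length.out = 10), matrix(1, 10, 1))
  b <- toy_trajectory(seq(0, 1, length.out = 11), matrix(1, 11, 1))
  expect_error(error_integral(a, b, 1), "same time grid")
})

test_that("quadrature is converged at the default grid", {
  coarse <- simple_reduction_pair(n_grid = 500)
  fine <- simple_reduction_pair(n_grid = 1000, horizon = coarse$horizon)
  e_coarse <- symmetric_error(coarse$reduced, coarse$full,
                              coarse$model$important)
  e_fine <- symmetric_error(fine$reduced, fine$full, fine$model$important)
  expect_lt(abs(e_coarse - e_fine), 1e-4)
})

test_that("trapezoid quadrature agrees with an adaptive quadrature oracle", {
  pair <- simple_reduction_pair(n_grid = 1000)
  e_trapz <- error_integral(pair$reduced, pair$full, pair$model$important)

  f_r <- lapply(c("X1", "X4"), function(cn) {
    stats::splinefun(pair$reduced$time, pair$reduced[[cn]])
  })
  f_f <- lapply(c("X1", "X4"), function(cn) {
    stats::splinefun(pair$full$time, pair$full[[cn]])
  })
  horizon <- pair$horizon
  e_adapt <- sum(vapply(1:2, function(i) {
    stats::integrate(function(t) abs(1 - f_r[[i]](t) / f_f[[i]](t)),
                     0, horizon, subdivisions = 2000,
                     rel.tol = 1e-10, abs.tol = 1e-12)$value
  }, 0)) / (horizon * 2)
  expect_lt(abs(e_trapz - e_adapt), 1e-4)
})

test_that("the dissimilarity matrix is the all-pairs symmetric error", {
  ex <- simple_example_fixture()
  cfg <- sampling_config("log_sd", 0.1, 3, seed = 9)
  draws <- sample_parameters(ex$reference, cfg)
  el <- eligible_complexes(ex$model)
  specs <- enumerate_reductions(el)[1:2]
  trajs <- list()
  for (i in 1:3) {
    ps <- nth_parameter_set(draws, i)
    ss <- steady_state(ex$model, ps)
    for (spec in specs) {
      red <- reduce_model(ex$model, ps, spec, ss)
      trajs[[paste0(i, "|", bitmask(spec))]] <-
        simulate_model(red, ps, 15, 200)
    }
  }
  D <- dissimilarity_matrix(trajs, ex$model$important)
  expect_identical(dim(D), c(6L, 6L))
  expect_identical(unname(diag(unclass(D))), rep(0, 6))
  expect_identical(unclass(D), t(unclass(D)))
  expect_true(all(D >= 0) && all(is.finite(D)))
  # spot-check against the scalar implementation
  for (pair in list(c(1, 2), c(2, 5), c(3, 6))) {
    expect_equal(
      D[pair[1], pair[2]],
      symmetric_error(trajs[[pair[1]]], trajs[[pair[2]]],
                      ex$model$important),
      tolerance = 1e-12
    )
  }
})

test_that("non-finite trajectories are excluded with a record", {
  time <- seq(0, 1, length.out = 5)
  good <- toy_trajectory(time, matrix(1, 5, 1))
  bad <- toy_trajectory(time, matrix(c(1, 2, Inf, 1, 1), 5, 1))
  expect_warning(
    D <- dissimilarity_matrix(list(a = good, b = bad, c = good), 1),
    "non-finite"
  )
  expect_identical(rownames(D), c("a", "c"))
  expect_identical(attr(D, "excluded"), "b")
})

test_that("dissimilarity files round-trip exactly", {
  set.seed(4)
  M <- matrix(stats::runif(25), 5, 5)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  dimnames(M) <- list(paste0("m", 1:5), paste0("m", 1:5))
  class(M) <- c("dissimilarity_matrix", class(M))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_dissimilarity(M, tmp)
  back <- read_dissimilarity(tmp)
  expect_identical(unclass(back), unclass(M)[,])
})
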