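test_that("eligible complexes are those free of important compounds", {
  ex <- simple_example_fixture()
  expect_identical(eligible_complexes(ex$model), c(2L, 3L))

  all_important <- network_model(
    ex$model$Z, ex$model$B, ex$model$boundary, important = 1:4
  )
  expect_length(eligible_complexes(all_important), 0)

  chain8 <- generate_fixture_network(8, 0, seed = 1)
  expect_identical(eligible_complexes(chain8$model), 2:7)
})

test_that("enumeration yields the full power set in canonical order", {
  specs6 <- enumerate_reductions(1:6)
  expect_length(specs6, 64)
  masks <- vapply(specs6, bitmask, "")
  expect_identical(anyDuplicated(masks), 0L)
  sizes <- vapply(specs6, function(s) s$size, 0L)
  expect_true(!is.unsorted(sizes))
  expect_identical(sum(sizes == 0), 1L)
  expect_identical(sum(sizes == 6), 1L)

  expect_length(enumerate_reductions(integer(0)), 1)
  specs2 <- enumerate_reductions(c(4L, 9L))
  expect_identical(lapply(specs2, function(s) s$reduced),
                   list(integer(0), 4L, 9L, c(4L, 9L)))
  expect_error(enumerate_reductions(1:17), "prefilter")
})

test_that("the empty reduction reproduces the full model trajectory", {
  ex <- simple_example_fixture()
  ss <- steady_state(ex$model, ex$reference)
  spec <- reduction_spec(integer(0), eligible_complexes(ex$model))
  red <- reduce_model(ex$model, ex$reference, spec, ss)
  a <- simulate_model(red, ex$reference, 15, 200)
  b <- simulate_model(ex$model, ex$reference, 15, 200)
  expect_equal(as.matrix(a[, -1]), as.matrix(b[, -1]), tolerance = 1e-7)
})

test_that("eliminating both intermediates gives the rerouted linear system", {
  ex <- simple_example_fixture()
  k <- ex$reference$params
  ss <- steady_state(ex$model, ex$reference)
  spec <- reduction_spec(c(2, 3), eligible_complexes(ex$model))
  red <- reduce_model(ex$model, ex$reference, spec, ss)
  tr <- simulate_model(red, ex$reference, 18, 200)

  # closed-form oracle for dx1 = k5 - (k1+k2) x1 ; dx4 = (k1+k2) x1 - k6 x4
  rhs <- function(x) c(k["k5"] - (k["k1"] + k["k2"]) * x[1],
                       (k["k1"] + k["k2"]) * x[1] - k["k6"] * x[2])
  oracle <- matexp_trajectory(rhs, c(0.4, 0.4), tr$time)
  expect_equal(as.matrix(tr[, c("X1", "X4")]), oracle, tolerance = 1e-6,
               ignore_attr = TRUE)

  # eliminated compounds satisfy their quasi-steady-state balance pointwise
  expect_equal(tr$X2, unname(k["k1"]) * tr$X1 / unname(k["k3"]),
               tolerance = 1e-8)
  expect_equal(tr$X3, unname(k["k2"]) * tr$X1 / unname(k["k4"]),
               tolerance = 1e-8)
})

test_that("single-complex elimination reroutes the flux through it", {
  ex <- simple_example_fixture()
  k <- ex$reference$params
  ss <- steady_state(ex$model, ex$reference)
  spec <- reduction_spec(2, eligible_complexes(ex$model))
  red <- reduce_model(ex$model, ex$reference, spec, ss)
  tr <- simulate_model(red, ex$reference, 18, 200)

  # oracle: x2 eliminated, so dx4 = k1 x1 + k4 x3 - k6 x4
  rhs <- function(x) c(
    k["k5"] - (k["k1"] + k["k2"]) * x[1],
    k["k2"] * x[1] - k["k4"] * x[2],
    k["k1"] * x[1] + k["k4"] * x[2] - k["k6"] * x[3]
  )
  oracle <- matexp_trajectory(rhs, c(0.4, 0.5, 0.4), tr$time)
  expect_equal(as.matrix(tr[, c("X1", "X3", "X4")]), oracle,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("reduction is set-based, independent of specification order", {
  fx <- generate_fixture_network(5, 0, seed = 5)
  el <- eligible_complexes(fx$model)
  ss <- steady_state(fx$model, fx$reference)
  pick <- el[c(1, 3)]
  a <- reduce_model(fx$model, fx$reference, reduction_spec(pick, el), ss)
  b <- reduce_model(fx$model, fx$reference, reduction_spec(rev(pick), el), ss)
  expect_identical(bitmask(a$spec), bitmask(b$spec))
  ta <- simulate_model(a, fx$reference, 10, 100)
  tb <- simulate_model(b, fx$reference, 10, 100)
  expect_identical(as.matrix(ta), as.matrix(tb))
})

test_that("specs outside the eligible or supported class are rejected", {
  ex <- simple_example_fixture()
  ss <- steady_state(ex$model, ex$reference)
  expect_error(reduction_spec(1, eligible_complexes(ex$model)),
               "outside the eligible set")

  # a two-compound complex is not a supported elimination target
  Z <- cbind(c(1, 0, 0), c(0, 1, 1), c(0, 0, 1))
  B <- cbind(c(-1, 1, 0), c(0, -1, 1))
  bd <- tibble::tibble(complex = c(1L, 3L), type = c("in", "out"),
                       param = c("b1", "b2"))
  m <- network_model(Z, B, bd, important = 1)
  ps <- parameter_set(c(k1 = 1, k2 = 1, b1 = 1, b2 = 1),
                      c(X1 = 1, X2 = 1, X3 = 1))
  el <- eligible_complexes(m)
  expect_identical(el, c(2L, 3L))
  expect_error(reduce_model(m, ps, reduction_spec(2, el), rep(1, 3)),
               "not single-compound")
  # complex 3 is single-compound but its compound also sits in complex 2
  expect_error(reduce_model(m, ps, reduction_spec(3, el), rep(1, 3)),
               "both reduced and retained")
})

test_that("greedy reduction respects its cut-off semantics", {
  ex <- simple_example_fixture()
  ss <- steady_state(ex$model, ex$reference)
  horizon <- evaluation_horizon(ex$model, ex$reference, ss)

  expect_length(greedy_reduce(ex$model, ex$reference, 0, horizon, 300), 0)

  all_in <- greedy_reduce(ex$model, ex$reference, Inf, horizon, 300)
  expect_setequal(all_in, eligible_complexes(ex$model))

  # a cut-off above the best single-step error admits both intermediates,
  # because the joint elimination error is far below the single-step one
  g <- greedy_reduce(ex$model, ex$reference, 0.06, horizon, 300)
  expect_setequal(g, c(2L, 3L))
  expect_lte(attr(g, "error"), 0.06)

  # the greedy endpoint is always one of the enumerated specs
  masks <- vapply(enumerate_reductions(eligible_complexes(ex$model)),
                  bitmask, "")
  g_mask <- bitmask(reduction_spec(g, eligible_complexes(ex$model)))
  expect_true(g_mask %in% masks)
})
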