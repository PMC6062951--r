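random_dissimilarity <- function(n, seed) {
  set.seed(seed)
  M <- matrix(stats::runif(n * n), n, n)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  dimnames(M) <- list(paste0("m", seq_len(n)), paste0("m", seq_len(n)))
  M
}

test_that("single linkage merges the hand-worked three-point example", {
  D <- matrix(0, 3, 3, dimnames = list(1:3, 1:3))
  D[1, 2] <- D[2, 1] <- 0.1
  D[1, 3] <- D[3, 1] <- 0.5
  D[2, 3] <- D[3, 2] <- 0.4
  tree <- single_linkage(D)
  expect_equal(tree$height, c(0.1, 0.4))
  # first merge joins leaves 1 and 2, the root adds leaf 3
  expect_setequal(tree$merge[1, ], c(-1, -2))
  expect_true(-3 %in% tree$merge[2, ])
})

test_that("two points merge at their distance", {
  D <- matrix(c(0, 0.3, 0.3, 0), 2, 2, dimnames = list(1:2, 1:2))
  tree <- single_linkage(D)
  expect_equal(tree$height, 0.3)
  expect_identical(sort(tree$order), 1:2)
})

test_that("merge heights match the brute-force oracle on random matrices", {
  for (case in list(c(5, 1), c(10, 2), c(25, 3), c(50, 4), c(50, 5))) {
    D <- random_dissimilarity(case[1], case[2])
    tree <- single_linkage(D)
    expect_true(!is.unsorted(tree$height))
    expect_equal(tree$height, brute_single_linkage_heights(D),
                 tolerance = 1e-12)
  }
})

test_that("non-finite dissimilarities are rejected", {
  D <- random_dissimilarity(4, 9)
  D[1, 2] <- D[2, 1] <- Inf
  expect_error(single_linkage(D), "finite")
})

test_that("leaf positions are a permutation and blocks stay contiguous", {
  for (seed in 6:8) {
    D <- random_dissimilarity(12, seed)
    pos <- leaf_positions(single_linkage(D))
    expect_setequal(pos$position, 1:12)
  }

  # two blocks: all within-block distances below all between-block ones
  set.seed(10)
  D <- matrix(stats::runif(36, 0.8, 1), 6, 6)
  D[1:3, 1:3] <- matrix(stats::runif(9, 0.05, 0.2), 3, 3)
  D[4:6, 4:6] <- matrix(stats::runif(9, 0.05, 0.2), 3, 3)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(paste0("m", 1:6), paste0("m", 1:6))
  pos <- leaf_positions(single_linkage(D))
  block1 <- sort(pos$position[1:3])
  block2 <- sort(pos$position[4:6])
  expect_identical(diff(block1), c(1L, 1L))
  expect_identical(diff(block2), c(1L, 1L))
})

test_that("the KS score equals the ECDF sup-difference oracle", {
  set.seed(21)
  for (rep in 1:20) {
    a <- sample.int(200, 30)
    b <- sample.int(200, 45)
    expect_equal(ks_score(a, b), ecdf_ks(a, b), tolerance = 1e-12)
    expect_identical(ks_score(a, b), ks_score(b, a))
  }
})

test_that("the KS score is invariant under monotone relabelling", {
  set.seed(22)
  a <- sample.int(500, 40)
  b <- sample.int(500, 40)
  f <- function(x) 3 * x^2 + 1      # strictly increasing on positives
  expect_identical(ks_score(a, b), ks_score(f(a), f(b)))
})

test_that("extreme KS configurations score 0 and 1", {
  expect_identical(ks_score(1:30, 1:30), 0)
  expect_identical(ks_score(1:30, 31:60), 1)
  expect_error(ks_score(numeric(0), 1:3), "empty")
})

test_that("scoring flags consistency and selects the best model", {
  # 3 reductions x 10 sets of synthetic positions: "10" fully separated,
  # "11" interleaved with the full model, "01" mildly shifted
  positions <- tibble::tibble(
    bitmask = rep(c("00", "11", "01", "10"), each = 10),
    set_id = rep(1:10, 4),
    position = c(
      seq(1, 28, by = 3),            # full
      seq(2, 29, by = 3),            # 11: interleaved -> low score
      seq(3, 30, by = 3),            # 01: interleaved -> low score
      31:40                          # 10: disjoint -> 1.00
    )
  )
  tab <- score_all(positions, alpha = 0.2)
  expect_identical(tab$score[tab$bitmask == "00"], 0)
  expect_identical(tab$score[tab$bitmask == "10"], 1)
  expect_true(all(tab$score >= 0 & tab$score <= 1))
  expect_identical(sum(tab$best), 1L)
  # the consistent model with the most reductions wins
  expect_identical(tab$bitmask[tab$best], "11")

  # consistency is monotone in alpha
  alphas <- c(0.05, 0.15, 0.4, 0.9)
  sets <- lapply(alphas, function(a) {
    t <- score_all(positions, alpha = a)
    t$bitmask[t$consistent]
  })
  for (i in seq_len(length(alphas) - 1)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  }

  # with nothing else consistent, the full model is best
  strict <- score_all(positions, alpha = 1e-9)
  expect_identical(strict$bitmask[strict$best], "00")
  lax <- score_all(dplyr::filter(positions, bitmask %in% c("00", "10")),
                   alpha = 0.2)
  expect_identical(lax$bitmask[lax$best], "00")

  expect_error(score_all(dplyr::filter(positions, bitmask != "00"), 0.2),
               "full model")
})

test_that("prefiltering keeps sub-threshold reductions plus the full model", {
  tab <- tibble::tibble(
    bitmask = c("00", "01", "10", "11"),
    size = c(0L, 1L, 1L, 2L),
    score = c(0, 1, 1, 0.17),
    consistent = c(TRUE, FALSE, FALSE, TRUE),
    best = c(FALSE, FALSE, FALSE, TRUE)
  )
  expect_identical(prefilter_reductions(tab, 0.5), c("00", "11"))
  expect_identical(prefilter_reductions(tab, 0), "00")
  expect_identical(prefilter_reductions(tab, 1.1),
                   c("00", "01", "10", "11"))
})

test_that("linkage trees export as a merge table", {
  D <- random_dissimilarity(5, 12)
  tree <- single_linkage(D)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_linkage(tree, tmp)
  back <- utils::read.table(tmp, header = TRUE, sep = "\t")
  expect_identical(nrow(back), 4L)
  expect_identical(back$height, tree$height)
  expect_identical(back$size[4], 5L)
})
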