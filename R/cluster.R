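#' Single-linkage clustering of a dissimilarity matrix
#'
#' Agglomerative clustering where the distance between two clusters is the
#' minimum pairwise symmetric error between their members; merge heights are
#' the merging distances and are non-decreasing.  The merge structure comes
#' from [stats::hclust()]; on top of it a canonical leaf ordering is fixed:
#' at every merge the child cluster that was created earlier is placed on
#' the left, with leaves counting as created at time zero ordered by label
#' index.
#'
#' @param D a `dissimilarity_matrix` (or any labelled symmetric matrix /
#'   `dist`).
#' @return An object of class `linkage_tree` with elements `merge`,
#'   `height`, `labels`, `order` (canonical) and `n_leaves`.
#' @export
single_linkage <- function(D) {
  d <- if (inherits(D, "dist")) D else stats::as.dist(unclass(D))
  if (any(!is.finite(d))) {
    stop("dissimilarities must be finite", call. = FALSE)
  }
  labels <- attr(d, "Labels") %||% as.character(seq_len(attr(d, "Size")))
  if (attr(d, "Size") < 2) {
    return(structure(
      list(merge = matrix(integer(0), 0, 2), height = numeric(0),
           labels = labels, order = 1L, n_leaves = 1L),
      class = "linkage_tree"
    ))
  }
  h <- stats::hclust(d, method = "single")
  structure(
    list(merge = h$merge, height = h$height, labels = labels,
         order = canonical_leaf_order(h$merge),
         n_leaves = length(labels)),
    class = "linkage_tree"
  )
}

# Left-to-right traversal with the earlier-created child on the left.
# hclust codes leaves as negative numbers and prior merges as positive row
# indices; a leaf (created at time 0) always precedes a merged cluster, two
# leaves order by label index, two clusters by merge step.
canonical_leaf_order <- function(merge) {
  n_merges <- nrow(merge)
  members <- vector("list", n_merges)
  leaf_members <- function(node) {
    if (node < 0) -node else members[[node]]
  }
  earlier <- function(a, b) {
    if (a < 0 && b < 0) return(-a < -b)
    if (a < 0) return(TRUE)
    if (b < 0) return(FALSE)
    a < b
  }
  for (s in seq_len(n_merges)) {
    a <- merge[s, 1]
    b <- merge[s, 2]
    if (!earlier(a, b)) {
      tmp <- a; a <- b; b <- tmp
    }
    members[[s]] <- c(leaf_members(a), leaf_members(b))
  }
  as.integer(members[[n_merges]])
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat("<linkage_tree> ", x$n_leaves, " leaves, ",
      length(x$height), " merges\n", sep = "")
  if (length(x$height) > 0) {
    cat("  merge heights: ", signif(min(x$height), 4), " ... ",
        signif(max(x$height), 4), "\n", sep = "")
  }
  invisible(x)
}

#' Dendrogram leaf positions
#'
#' Every model's position (1..N) in the canonical dendrogram leaf ordering;
#' these positions are the sample unit for the Kolmogorov-Smirnov
#' consistency score.
#'
#' @param tree a `linkage_tree` from [single_linkage()].
#' @return A tibble with columns `label` and `position`.
#' @export
leaf_positions <- function(tree) {
  stopifnot(inherits(tree, "linkage_tree"))
  pos <- integer(tree$n_leaves)
  pos[tree$order] <- seq_len(tree$n_leaves)
  tibble::tibble(label = tree$labels, position = pos)
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The supremum absolute difference between the empirical distribution
#' functions of two position samples; the consistency score of a reduction
#' against the full model.  No p-value is involved: the statistic itself is
#' thresholded.
#'
#' @param positions_a,positions_b non-empty numeric samples.
#' @return Scalar in `[0, 1]`.
#' @export
ks_score <- function(positions_a, positions_b) {
  if (length(positions_a) == 0 || length(positions_b) == 0) {
    stop("cannot score an empty position sample", call. = FALSE)
  }
  unname(suppressWarnings(
    stats::ks.test(positions_a, positions_b)$statistic
  ))
}

#' Score every reduction against the full model
#'
#' Collects each reduction's dendrogram positions across all parameter
#' sets, computes its KS score against the full model's positions, flags
#' reductions scoring below `alpha` as consistent, and marks the best
#' model: the consistent reduction clamping the most complexes, ties broken
#' by the lowest score (then lexicographically smallest bitmask).  The full
#' model's own score is 0 by definition, so it is always consistent and is
#' the best model when nothing else is.
#'
#' @param positions a tibble with columns `bitmask`, `set_id` and
#'   `position` (one row per model), e.g. [leaf_positions()] joined to the
#'   model labels.
#' @param alpha consistency threshold on the KS score.
#' @return A `reduction_scores` tibble with columns `bitmask`, `size`,
#'   `score`, `consistent`, `best`.
#' @export
score_all <- function(positions, alpha = 0.2) {
  stopifnot(all(c("bitmask", "position") %in% names(positions)))
  masks <- unique(positions$bitmask)
  full_mask <- strrep("0", nchar(masks[1]))
  if (!full_mask %in% masks) {
    stop("the full model (all-zero bitmask) is missing from the positions",
         call. = FALSE)
  }
  full_pos <- positions$position[positions$bitmask == full_mask]

  scores <- purrr::map_dbl(masks, function(m) {
    if (m == full_mask) return(0)
    ks_score(positions$position[positions$bitmask == m], full_pos)
  })
  out <- tibble::tibble(
    bitmask = masks,
    size = vapply(strsplit(masks, ""),
                  function(b) sum(b == "1"), 0L),
    score = scores,
    consistent = scores < alpha
  )
  out <- dplyr::arrange(out, .data$size, .data$bitmask)
  out$best <- FALSE
  cand <- dplyr::filter(out, .data$consistent)
  cand <- dplyr::arrange(cand, dplyr::desc(.data$size), .data$score,
                         .data$bitmask)
  if (nrow(cand) > 0) out$best[out$bitmask == cand$bitmask[1]] <- TRUE
  attr(out, "alpha") <- alpha
  class(out) <- c("reduction_scores", class(out))
  out
}

#' Carry forward only promising reductions
#'
#' After a pilot run, keeps the reductions whose KS score falls below the
#' prefilter threshold (the full model is always retained) so a larger
#' sampling run only needs to simulate the survivors.
#'
#' @param scores a `reduction_scores` table from [score_all()].
#' @param threshold prefilter threshold on the KS score.
#' @return Character vector of surviving bitmasks.
#' @export
prefilter_reductions <- function(scores, threshold) {
  full_mask <- strrep("0", nchar(scores$bitmask[1]))
  keep <- scores$bitmask[scores$score < threshold]
  sort(unique(c(full_mask, keep)))
}

#' Write a linkage tree as a merge table
#'
#' One row per merge: left id, right id, height, new cluster size.
#' Negative ids are leaves, positive ids earlier merges — the same coding
#' as [stats::hclust()].
#'
#' @param tree a `linkage_tree`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_linkage <- function(tree, path) {
  sizes <- integer(nrow(tree$merge))
  size_of <- function(node, sizes) if (node < 0) 1L else sizes[node]
  for (s in seq_len(nrow(tree$merge))) {
    sizes[s] <- size_of(tree$merge[s, 1], sizes) +
      size_of(tree$merge[s, 2], sizes)
  }
  df <- data.frame(
    left = tree$merge[, 1], right = tree$merge[, 2],
    height = tree$height, size = sizes
  )
  write_full_precision(df, path)
  invisible(path)
}
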