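#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a score table
#'
#' @param x a `reduction_scores` object from [score_all()] or
#'   [run_reduction_analysis()].
#' @param ... unused.
#' @return A plain tibble with one row per reduction: `bitmask`, `size`,
#'   `score`, `consistent`, `best`.
#' @export
tidy.reduction_scores <- function(x, ...) {
  out <- x
  attributes(out)[c("tree", "positions", "config", "dissimilarity",
                    "horizon", "n_models", "alpha")] <- NULL
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out
}

#' One-line summary of an analysis
#'
#' @inheritParams tidy.reduction_scores
#' @return A one-row tibble: number of reductions and models, threshold,
#'   horizon, number of consistent reductions, and the best bitmask.
#' @export
glance.reduction_scores <- function(x, ...) {
  tibble::tibble(
    n_reductions = nrow(x),
    n_models = attr(x, "n_models") %||% NA_integer_,
    alpha = attr(x, "alpha") %||% NA_real_,
    horizon = attr(x, "horizon") %||% NA_real_,
    n_consistent = sum(x$consistent),
    best = x$bitmask[x$best][1]
  )
}

#' Plot reduction scores
#'
#' Lollipop chart of KS scores per reduction bitmask, ordered by reduction
#' size, with the consistency threshold drawn as a dashed line; the best
#' model is emphasised.
#'
#' @param object a `reduction_scores` object.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.reduction_scores <- function(object, ...) {
  df <- tidy(object)
  df$bitmask <- factor(df$bitmask, levels = df$bitmask[order(df$size, df$bitmask)])
  alpha <- attr(object, "alpha") %||% 0.2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bitmask, y = .data$score)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$bitmask, yend = 0),
                          colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$consistent,
                                     shape = .data$best), size = 3) +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed") +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 8)) +
    ggplot2::labs(x = "reduction (bitmask over eligible complexes)",
                  y = "Kolmogorov-Smirnov score",
                  colour = paste0("consistent (α = ", alpha, ")"),
                  shape = "best model") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Dendrogram of a clustered analysis
#'
#' Draws the single-linkage dendrogram in the canonical leaf order with
#' each leaf coloured by its reduction, the direct visual check that a
#' reduction does (or does not) mix with the full model.
#'
#' @param tree a `linkage_tree` from [single_linkage()].
#' @param positions optional tibble with columns `label` and `bitmask`
#'   (e.g. attribute `"positions"` of [run_reduction_analysis()]); colours
#'   leaves by bitmask.
#' @return A ggplot.
#' @export
plot_dendrogram <- function(tree, positions = NULL) {
  stopifnot(inherits(tree, "linkage_tree"))
  n <- tree$n_leaves
  pos <- integer(n)
  pos[tree$order] <- seq_len(n)
  # node coordinates: leaves at height 0, merges at their height, x at the
  # mean of the children
  xs <- numeric(nrow(tree$merge))
  segs <- vector("list", nrow(tree$merge))
  node_x <- function(v) if (v < 0) pos[-v] else xs[v]
  node_y <- function(v) if (v < 0) 0 else tree$height[v]
  for (s in seq_len(nrow(tree$merge))) {
    a <- tree$merge[s, 1]; b <- tree$merge[s, 2]
    xa <- node_x(a); xb <- node_x(b)
    h <- tree$height[s]
    xs[s] <- (xa + xb) / 2
    segs[[s]] <- tibble::tibble(
      x = c(xa, xb, min(xa, xb)),
      xend = c(xa, xb, max(xa, xb)),
      y = c(node_y(a), node_y(b), h),
      yend = c(h, h, h)
    )
  }
  seg_df <- dplyr::bind_rows(segs)
  leaves <- tibble::tibble(label = tree$labels, x = pos, y = 0)
  if (!is.null(positions)) {
    leaves <- dplyr::left_join(
      leaves, dplyr::select(positions, "label", "bitmask"), by = "label"
    )
  }
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg_df,
      ggplot2::aes(x = .data$x, xend = .data$xend,
                   y = .data$y, yend = .data$yend),
      colour = "grey40"
    ) +
    ggplot2::labs(x = "dendrogram position", y = "symmetric error") +
    ggplot2::theme_minimal()
  if (!is.null(positions)) {
    p <- p + ggplot2::geom_point(
      data = leaves,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$bitmask),
      size = 1.5
    ) + ggplot2::labs(colour = "reduction")
  }
  p
}

#' @export
print.reduction_scores <- function(x, ...) {
  cat("# Reduction scores (alpha = ", attr(x, "alpha") %||% NA,
      if (!is.null(attr(x, "n_models"))) {
        paste0(", ", attr(x, "n_models"), " models clustered")
      } else "",
      ")\n", sep = "")
  print(tidy(x), ...)
  best <- x$bitmask[x$best]
  if (length(best) > 0) cat("# best model: [", best, "]\n", sep = "")
  invisible(x)
}

#' @importFrom rlang .data
NULL
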