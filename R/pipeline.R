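#' Run the full reduction-evaluation analysis
#'
#' The end-to-end procedure: sample parameter sets around the reference,
#' compute the full model's steady state per set, build and simulate every
#' candidate reduction for every set on a shared time grid, assemble the
#' all-pairs symmetric-error matrix, cluster by single linkage, and score
#' every reduction's dendrogram positions against the full model's with the
#' Kolmogorov-Smirnov statistic.  The evaluation horizon `T` is resolved
#' once, from the reference parameter set, and shared by all models.
#'
#' With `pilot_n` set, a two-stage run is performed: a pilot with `pilot_n`
#' sets over all reductions, then the main run with `n_sets` fresh sets over
#' only the reductions whose pilot score fell below `prefilter`.
#'
#' @param model a [network_model()].
#' @param reference the reference [parameter_set()].
#' @param n_sets number of parameter sets in the (main) run.
#' @param mode,spread sampling scheme, see [sampling_config()].
#' @param seed integer seed for parameter sampling.
#' @param alpha consistency threshold on the KS score.
#' @param horizon evaluation horizon `T`; `NULL` resolves it via
#'   [evaluation_horizon()] at the reference parameters.
#' @param n_grid shared uniform grid size on `[0, T]`.
#' @param prefilter KS threshold used between the two stages.
#' @param pilot_n pilot-stage sample count (`NULL` for a single stage).
#' @param model_cap refuse single-stage runs with more than this many
#'   models (`n_sets * 2^c`).
#' @param out_dir optional directory: parameter table, dissimilarity
#'   matrix, linkage table, leaf positions, score table, resolved
#'   configuration and a run log are written there.
#' @param workers number of parallel workers for the simulation stage
#'   (forked via [parallel::mclapply()]; 1 = serial).
#' @param rtol,atol solver tolerances.
#' @param epsilon denominator floor of the error integral.
#' @param keep_matrix attach the dissimilarity matrix to the result
#'   (attribute `"dissimilarity"`); off by default since it is quadratic in
#'   the number of models.
#'
#' @return A `reduction_scores` tibble (see [score_all()]) with attributes
#'   `"tree"` (the `linkage_tree`), `"positions"` (per-model leaf
#'   positions), `"horizon"`, `"n_models"` and `"config"`.
#' @examples
#' \donttest{
#' ex <- build_simple_example()
#' scores <- run_reduction_analysis(ex$model, ex$reference,
#'                                  n_sets = 20, n_grid = 200, seed = 1)
#' scores
#' }
#' @export
run_reduction_analysis <- function(model, reference,
                                   n_sets = 100,
                                   mode = c("log_sd", "natural_cv"),
                                   spread = 0.1,
                                   seed = 1L,
                                   alpha = 0.2,
                                   horizon = NULL,
                                   n_grid = 1000,
                                   prefilter = 0.5,
                                   pilot_n = NULL,
                                   model_cap = 10000,
                                   out_dir = NULL,
                                   workers = 1L,
                                   rtol = 1e-8, atol = 1e-10,
                                   epsilon = 1e-12,
                                   keep_matrix = FALSE) {
  mode <- match.arg(mode)
  eligible <- eligible_complexes(model)
  specs <- enumerate_reductions(eligible)
  if (is.null(pilot_n) && n_sets * length(specs) > model_cap) {
    stop("this run would simulate ", n_sets * length(specs),
         " models (cap ", model_cap, "); enable two-stage prefiltering ",
         "with `pilot_n` or raise `model_cap`", call. = FALSE)
  }

  if (is.null(horizon)) {
    horizon <- evaluation_horizon(model, reference, rtol = rtol, atol = atol)
  }

  log_lines <- c(
    paste0("model: ", model$name),
    paste0("eligible complexes (c): ", length(eligible)),
    paste0("mode: ", mode, "  spread: ", spread, "  seed: ", seed),
    paste0("resolved horizon T: ", format(horizon))
  )

  if (!is.null(pilot_n)) {
    pilot_cfg <- sampling_config(mode, spread, pilot_n, seed)
    pilot_draws <- sample_parameters(reference, pilot_cfg)
    pilot <- cluster_and_score(
      model, reference, pilot_draws, specs, horizon, n_grid,
      alpha, rtol, atol, epsilon, workers
    )
    keep <- prefilter_reductions(pilot$scores, prefilter)
    specs <- purrr::keep(specs, function(s) bitmask(s) %in% keep)
    log_lines <- c(
      log_lines,
      paste0("pilot: ", pilot_n, " sets, prefilter ", prefilter,
             " -> ", length(specs), " reductions retained")
    )
    seed <- seed + 1L
  }

  cfg <- sampling_config(mode, spread, n_sets, seed)
  draws <- sample_parameters(reference, cfg)
  res <- cluster_and_score(
    model, reference, draws, specs, horizon, n_grid,
    alpha, rtol, atol, epsilon, workers
  )
  scores <- res$scores

  n_models <- as.integer(n_sets * length(specs))
  attr(scores, "tree") <- res$tree
  attr(scores, "positions") <- res$positions
  attr(scores, "horizon") <- horizon
  attr(scores, "n_models") <- n_models
  config <- list(
    model = model$name, n_sets = as.integer(n_sets), mode = mode, spread = spread,
    seed = cfg$seed, alpha = alpha, horizon = horizon, n_grid = n_grid,
    prefilter = if (is.null(pilot_n)) NA else prefilter,
    pilot_n = pilot_n %||% NA, rtol = rtol, atol = atol, epsilon = epsilon,
    n_models = n_models
  )
  attr(scores, "config") <- config
  if (keep_matrix) attr(scores, "dissimilarity") <- res$D

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_parameter_table(draws, file.path(out_dir, "parameter_sets.tsv"))
    write_dissimilarity(res$D, file.path(out_dir, "dissimilarity.tsv"))
    write_linkage(res$tree, file.path(out_dir, "linkage.tsv"))
    write_full_precision(as.data.frame(res$positions),
                         file.path(out_dir, "leaf_positions.tsv"))
    write_full_precision(as.data.frame(scores),
                         file.path(out_dir, "scores.tsv"))
    writeLines(yaml::as.yaml(config, precision = 17),
               file.path(out_dir, "config_resolved.yaml"))
    writeLines(c(log_lines,
                 paste0("models clustered: ", n_models),
                 paste0("best model: ",
                        scores$bitmask[scores$best][1] %||% NA)),
               file.path(out_dir, "run.log"))
  }
  scores
}

# Simulate every (parameter set, reduction) pair on the shared grid, build
# the dissimilarity matrix, cluster and score.  Labels are "<set>|<mask>".
cluster_and_score <- function(model, reference, draws, specs, horizon,
                              n_grid, alpha, rtol, atol, epsilon, workers) {
  masks <- vapply(specs, bitmask, "")
  sim_one_set <- function(i) {
    ps <- nth_parameter_set(draws, i)
    ss <- steady_state(model, ps, rtol = rtol, atol = atol)
    trajs <- lapply(specs, function(spec) {
      red <- reduce_model(model, ps, spec, ss)
      simulate_model(red, ps, horizon, n_grid, rtol, atol)
    })
    names(trajs) <- paste0(draws$set_id[i], "|", masks)
    trajs
  }
  sets <- seq_len(nrow(draws))
  per_set <- if (workers > 1L) {
    parallel::mclapply(sets, sim_one_set, mc.cores = workers)
  } else {
    lapply(sets, sim_one_set)
  }
  trajectories <- do.call(c, per_set)

  D <- dissimilarity_matrix(trajectories, model$important, epsilon)
  tree <- single_linkage(D)
  positions <- leaf_positions(tree)
  positions <- tidyr::separate(positions, "label",
                               into = c("set_id", "bitmask"),
                               sep = "\\|", remove = FALSE)
  positions$set_id <- as.integer(positions$set_id)
  list(scores = score_all(positions, alpha), tree = tree,
       positions = positions, D = D)
}

#' Model labels of an analysis
#'
#' The `(parameter set, reduction)` label grid an analysis clusters: one
#' row per model, `n_sets * 2^c` in total.
#'
#' @param n_sets number of parameter sets.
#' @param specs list of [reduction_spec()]s (e.g. from
#'   [enumerate_reductions()]).
#' @return Tibble with columns `set_id`, `bitmask` and `label`.
#' @export
analysis_labels <- function(n_sets, specs) {
  grid <- tidyr::crossing(
    set_id = seq_len(n_sets),
    bitmask = vapply(specs, bitmask, "")
  )
  grid$label <- paste0(grid$set_id, "|", grid$bitmask)
  grid
}

#' Generate a random linear mass-action fixture network
#'
#' Emits a synthetic network with the same structural assumptions as the
#' bundled example: single-compound complexes, a chain of irreversible
#' mass-action conversions from the first to the last compound with
#' `n_branches` additional shortcut reactions, one constant inflow into the
#' first compound and one first-order outflow from the last, and
#' `important = {first, last}`.  Every compound drains towards the outflow,
#' so the network is asymptotically stable and has a steady state.
#'
#' @param n_chain_compounds number of compounds (at least 2).
#' @param n_branches number of extra shortcut reactions `i -> j`,
#'   `j > i + 1`.
#' @param seed integer seed; the same seed reproduces the same network and
#'   file byte for byte.
#' @param path optional file path; if given the network definition is
#'   written there with [write_network()].
#' @return A list with components `model` and `reference`.
#' @export
generate_fixture_network <- function(n_chain_compounds, n_branches = 0,
                                     seed = 1L, path = NULL) {
  stopifnot(n_chain_compounds >= 2)
  n <- n_chain_compounds
  pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  pairs <- pairs[pairs$to > pairs$from + 1, , drop = FALSE]
  if (n_branches > nrow(pairs)) {
    stop("at most ", nrow(pairs), " shortcut branches fit this chain",
         call. = FALSE)
  }
  drawn <- with_preserved_seed(seed, {
    sel <- if (n_branches > 0) {
      pairs[sample.int(nrow(pairs), n_branches), , drop = FALSE]
    } else {
      pairs[0, , drop = FALSE]
    }
    n_rxn <- (n - 1) + n_branches
    list(
      branches = sel,
      rates = stats::rlnorm(n_rxn + 2, meanlog = log(0.3), sdlog = 0.5),
      x0 = stats::runif(n, 0.1, 1)
    )
  })
  from <- c(seq_len(n - 1), drawn$branches$from)
  to <- c(seq_len(n - 1) + 1, drawn$branches$to)
  n_rxn <- length(from)
  B <- matrix(0L, n, n_rxn)
  for (j in seq_len(n_rxn)) {
    B[from[j], j] <- -1L
    B[to[j], j] <- 1L
  }
  model <- network_model(
    Z = diag(n), B = B,
    boundary = tibble::tibble(
      complex = c(1L, n),
      type = c("in", "out"),
      param = paste0("k", n_rxn + 1:2)
    ),
    important = c(1L, n),
    compound_names = paste0("X", seq_len(n)),
    name = paste0("fixture_", n, "c_", n_branches, "b_seed", seed)
  )
  reference <- parameter_set(
    params = stats::setNames(drawn$rates, paste0("k", seq_len(n_rxn + 2))),
    x0 = stats::setNames(round(drawn$x0, 6), model$compound_names)
  )
  if (!is.null(path)) write_network(model, reference, path)
  list(model = model, reference = reference)
}
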