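#' Configure a parameter-uncertainty sampling scheme
#'
#' Two log-normal schemes are supported, matching the two natural ways of
#' centring the distribution on a reference value:
#'
#' * `"log_sd"` — parameters are log-normal with log-mean `ln(ref)` and log
#'   standard deviation `spread` (uncertainty stated on the log scale).
#' * `"natural_cv"` — parameters are log-normal with natural-scale mean
#'   `ref` and natural-scale standard deviation `ref / spread`, i.e.
#'   `spread` is the inverse coefficient of variation; moment matching
#'   gives \eqn{\sigma^2_{\log} = \ln(1 + 1/s^2)} and
#'   \eqn{\mu_{\log} = \ln(ref) - \sigma^2_{\log}/2}.
#'
#' @param mode `"log_sd"` or `"natural_cv"`.
#' @param spread positive spread parameter (log-sd, or the scaling divisor
#'   `s`).
#' @param n_sets number of parameter sets to draw.
#' @param seed integer RNG seed.
#' @return An object of class `sampling_config`.
#' @export
sampling_config <- function(mode = c("log_sd", "natural_cv"),
                            spread, n_sets, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(spread > 0, n_sets >= 1)
  structure(
    list(mode = mode, spread = spread, n_sets = as.integer(n_sets),
         seed = as.integer(seed)),
    class = "sampling_config"
  )
}

#' Draw parameter sets around a reference set
#'
#' Each positive parameter is sampled independently from the log-normal law
#' selected by the config; parameters whose reference value is exactly zero
#' are emitted as zero (a structurally absent rate stays absent).  Initial
#' values are copied unchanged from the reference: only rate parameters are
#' treated as uncertain.
#'
#' @param reference a [parameter_set()].
#' @param config a [sampling_config()].
#' @return A tibble with a `set_id` column and one column per parameter;
#'   the reference initial values are attached as attribute `"x0"`.
#' @export
sample_parameters <- function(reference, config) {
  stopifnot(inherits(reference, "parameter_set"),
            inherits(config, "sampling_config"))
  ref <- reference$params
  if (any(ref < 0)) stop("negative reference parameter", call. = FALSE)
  n <- config$n_sets

  draws <- with_preserved_seed(config$seed, {
    vapply(ref, function(r) {
      if (r == 0) return(rep(0, n))
      if (config$mode == "log_sd") {
        stats::rlnorm(n, meanlog = log(r), sdlog = config$spread)
      } else {
        sdlog2 <- log(1 + 1 / config$spread^2)
        stats::rlnorm(n, meanlog = log(r) - sdlog2 / 2, sdlog = sqrt(sdlog2))
      }
    }, numeric(n))
  })
  if (n == 1) draws <- matrix(draws, nrow = 1, dimnames = list(NULL, names(ref)))

  out <- tibble::as_tibble(as.data.frame(draws))
  out <- dplyr::bind_cols(tibble::tibble(set_id = seq_len(n)), out)
  attr(out, "x0") <- reference$x0
  attr(out, "config") <- config
  out
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream.
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Turn one row of a sampled parameter table into a parameter set
#'
#' @param draws a tibble from [sample_parameters()].
#' @param i row index.
#' @return A [parameter_set()] tagged with its `set_id`.
#' @export
nth_parameter_set <- function(draws, i) {
  row <- draws[i, setdiff(names(draws), "set_id"), drop = FALSE]
  ps <- parameter_set(params = unlist(row), x0 = attr(draws, "x0"))
  attr(ps, "set_id") <- draws$set_id[i]
  ps
}

#' Build one sampling config per spread value
#'
#' Derives deterministic per-config seeds from a master seed (master plus
#' the spread's position in the plan) so partial reruns reproduce exactly.
#'
#' @param spreads numeric vector of spread values (e.g. the scaling
#'   divisors `3, 5, 10, 20, 50, 100`).
#' @param mode,n_sets passed to [sampling_config()].
#' @param master_seed integer master seed.
#' @return List of [sampling_config()] objects, one per spread.
#' @export
sampling_plan <- function(spreads, mode = "natural_cv", n_sets = 100,
                          master_seed = 1L) {
  purrr::imap(
    as.numeric(spreads),
    function(s, i) sampling_config(mode, s, n_sets, seed = master_seed + i)
  )
}

#' Write / read a sampled parameter table
#'
#' Tab-delimited, one row per parameter set, `set_id` first; values
#' round-trip at full double precision.  Initial values are stored in
#' `# x0:` header comment lines and restored on read.
#'
#' @param draws tibble from [sample_parameters()].
#' @param path file path.
#' @return `path` (writer, invisibly) or the tibble (reader).
#' @export
write_parameter_table <- function(draws, path) {
  x0 <- attr(draws, "x0")
  header <- paste0("# x0: ", paste(names(x0), sprintf("%.17g", x0),
                                   sep = "=", collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  df <- as.data.frame(draws)
  num <- vapply(df, is.numeric, TRUE) & names(df) != "set_id"
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_parameter_table
#' @export
read_parameter_table <- function(path) {
  header <- readLines(path, n = 1)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE)
  out <- tibble::as_tibble(df)
  pairs <- strsplit(strsplit(sub("^# x0: ", "", header), " ")[[1]], "=")
  x0 <- stats::setNames(
    vapply(pairs, function(p) as.numeric(p[2]), 0),
    vapply(pairs, `[`, "", 1)
  )
  attr(out, "x0") <- x0
  out
}
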