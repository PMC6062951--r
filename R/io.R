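#' Read and write network definition files
#'
#' A network definition is a YAML document with blocks `compounds`,
#' `complexes` (sparse stoichiometry per complex), `reactions` (substrate
#' complex, product complex, rate parameter, optional kinetic modifier
#' identifier), `boundary` (per-complex inflow/outflow entries), `important`,
#' `parameters` (reference values) and `initial_values`.  Files written by
#' [write_network()] read back to an identical model, and re-writing a file
#' produced by the writer reproduces it byte for byte.
#'
#' @param path file path.
#' @return `read_network()`: a list with components `model` and `reference`,
#'   as for [build_simple_example()].  `write_network()`: `path`, invisibly.
#' @export
read_network <- function(path) {
  doc <- yaml::read_yaml(path)
  compounds <- as.character(doc$compounds)
  cx_names <- names(doc$complexes)
  Z <- matrix(0L, length(compounds), length(cx_names),
              dimnames = list(compounds, cx_names))
  for (cx in cx_names) {
    st <- doc$complexes[[cx]]
    Z[match(names(st), compounds), cx] <- as.integer(unlist(st))
  }
  rxn_names <- names(doc$reactions)
  B <- matrix(0L, length(cx_names), length(rxn_names))
  rate_params <- character(length(rxn_names))
  for (j in seq_along(rxn_names)) {
    r <- doc$reactions[[j]]
    B[match(r$substrate, cx_names), j] <- -1L
    B[match(r$product, cx_names), j] <- 1L
    rate_params[j] <- r$rate
  }
  boundary <- if (length(doc$boundary) > 0) {
    tibble::tibble(
      complex = vapply(doc$boundary,
                       function(b) match(b$complex, cx_names), 0L),
      type = vapply(doc$boundary, function(b) b$type, ""),
      param = vapply(doc$boundary, function(b) b$param, "")
    )
  } else {
    tibble::tibble(complex = integer(0), type = character(0),
                   param = character(0))
  }
  model <- network_model(
    Z = Z, B = B, boundary = boundary,
    important = as.character(doc$important),
    rate_params = rate_params,
    compound_names = compounds, complex_names = cx_names,
    reaction_names = rxn_names,
    name = doc$name %||% "network"
  )
  reference <- parameter_set(
    params = unlist(doc$parameters),
    x0 = stats::setNames(as.numeric(unlist(doc$initial_values[compounds])),
                         compounds)
  )
  list(model = model, reference = reference)
}

#' @rdname read_network
#' @param model a [network_model()].
#' @param reference the reference [parameter_set()].
#' @export
write_network <- function(model, reference, path) {
  complexes <- lapply(seq_len(ncol(model$Z)), function(j) {
    nz <- which(model$Z[, j] != 0)
    as.list(stats::setNames(as.integer(model$Z[nz, j]),
                            model$compound_names[nz]))
  })
  names(complexes) <- model$complex_names
  reactions <- lapply(seq_along(model$reaction_names), function(j) {
    list(
      substrate = model$complex_names[model$substrate[j]],
      product = model$complex_names[model$product[j]],
      rate = model$rate_params[j]
    )
  })
  names(reactions) <- model$reaction_names
  boundary <- lapply(seq_len(nrow(model$boundary)), function(r) {
    list(
      complex = model$complex_names[model$boundary$complex[r]],
      type = model$boundary$type[r],
      param = model$boundary$param[r]
    )
  })
  doc <- list(
    name = model$name,
    compounds = as.list(model$compound_names),
    complexes = complexes,
    reactions = reactions,
    boundary = boundary,
    important = as.list(model$compound_names[model$important]),
    parameters = as.list(reference$params),
    initial_values = as.list(reference$x0)
  )
  writeLines(yaml::as.yaml(doc, precision = 17), path)
  invisible(path)
}
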