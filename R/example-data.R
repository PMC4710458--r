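#' Published per-strategy variable-importance ranks (example data)
#'
#' A worked example for [aggregate_ranks()]: within-strategy importance
#' ranks of 20 GIS-derived catchment predictors of stream-fish
#' assemblage composition under five modelling strategies (single
#' species ensemble, discriminant-analysis and random-forest community
#' classifiers, and the two multi-response models). A blank cell means
#' the strategy did not retain the variable.
#'
#' @return matrix of ranks (variables x strategies) with NA for
#'   unretained variables.
#' @examples
#' head(aggregate_ranks(example_importance_ranks()))
#' @export
example_importance_ranks <- function() {
  path <- system.file("extdata", "variable_importance_ranks.csv",
                      package = "refstream", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L])
  rownames(m) <- df[[1L]]
  m
}
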