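#' @useDynLib preyweb, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom data.table := .N
#' @import data.table
#' @keywords internal
"_PACKAGE"

utils::globalVariables(c(
  ".", "bases", "count", "specimen", "predator", "prey", "sample_id",
  "species", "setting", "n_reads", "consumed", "qual"
))
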