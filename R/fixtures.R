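#' Packaged worked-example tables
#'
#' Per-cultivar summary tables (mean, sd, n = 3) for seven conventional apple
#' cultivars, transcribed from a published composition study: phenolic
#' compounds (mg/kg FW), antioxidant assay endpoints (TPC as mg GAE/kg FW,
#' DPPH IC50 as ug/mL, FRAP as mg AAE/kg FW), organic acids plus phosphate
#' (mg/kg FW) and sugars/sugar alcohols (g/kg FW).  Analytes not detected in
#' a cultivar carry the `"n.d."` token.
#'
#' @param table One of `"phenolics"`, `"assays"`, `"organic_acids"`,
#'   `"sugars"`.
#' @return A `cultivar_summary` data frame (see [read_summary_table()]).
#' @examples
#' head(apple_summaries("phenolics"))
#' @export
apple_summaries <- function(table = c("phenolics", "assays", "organic_acids",
                                      "sugars")) {
  table <- match.arg(table)
  read_summary_table(system.file("extdata", paste0(table, ".csv"),
                                 package = "pomochem", mustWork = TRUE))
}

#' Packaged trained network weight tables
#'
#' Paths to the published 12-11-2 multilayer-perceptron weight tables:
#' the input-to-hidden matrix W1 with its bias row, and the hidden-to-output
#' matrix W2 with its bias column.  Load with [load_weight_tables()].
#'
#' @return Named character vector with elements `w1` and `w2`.
#' @export
apple_weight_paths <- function() {
  c(w1 = system.file("extdata", "weights_input_hidden.csv",
                     package = "pomochem", mustWork = TRUE),
    w2 = system.file("extdata", "weights_hidden_output.csv",
                     package = "pomochem", mustWork = TRUE))
}

# Canonical variable orders for the two multivariate analyses.
phenolic_pca_variables <- function() {
  c("A", "GA", "nCA", "C", "CA", "pCA", "pCB2", "E", "Q3ga", "Q3gl",
    "P", "Q3ru", "Q3rh")
}
acid_sugar_pca_variables <- function() {
  c("QA", "LA", "ShA", "GA", "SuA", "MA", "FA", "OA", "P", "CA",
    "MI", "S", "Gal", "Glu", "Fru", "Suc")
}

mlp_input_names <- function() {
  c("A", "GA", "C", "CA", "pCA", "pCB2", "E", "Q3ga", "Q3gl", "P",
    "Q3ru", "Q3rh")
}
mlp_output_names <- function() c("DPPH", "FRAP")
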