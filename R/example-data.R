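## Bundled worked-example tables from a published mouse granulocytic
## differentiation screen (CSH3 / MLL-ENL cell model), used as fixed
## reference inputs in examples and tests.

#' Bundled candidate-lncRNA table
#'
#' Fourteen candidate lncRNAs that were both essential (top intramodular
#' degree in their co-expression module) and differentially expressed
#' between normally differentiating and differentiation-arrested cells.
#' `enriched_in` is `normal_diff` or `diff_arrest`; `adj_p` is the reported
#' differential-expression p-value.
#'
#' @return Data frame with `gene_id`, `symbol`, `chromosome`,
#'   `scaled_degree`, `enriched_in`, `adj_p`.
#' @export
example_candidate_table <- function() {
  utils::read.delim(system.file("extdata", "myeloid_candidate_lncRNAs.tsv",
                                package = "coexscreen"),
                    stringsAsFactors = FALSE)
}

#' Bundled regulator-correlation table
#'
#' Pearson correlations of 19 transcription factors (plus the target lncRNA
#' Gdal1 itself) with Gdal1 synthesis rate over a 6-point nascent-RNA time
#' course, with the reported correlation-test p-values.
#'
#' @return Data frame with `gene_id`, `symbol`, `r`, `p`.
#' @export
example_regulator_table <- function() {
  utils::read.delim(system.file("extdata", "gdal1_regulator_correlations.tsv",
                                package = "coexscreen"),
                    stringsAsFactors = FALSE)
}
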