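## Differential expression: ingestion of external result tables under an
## adjusted-p threshold contract, a built-in Welch-t/BH test so fully
## synthetic pipelines need no external tool, and set algebra helpers.

#' Load a differential-expression result table
#'
#' Parses a TSV of per-gene DE results and flags the significant subset at
#' an inclusive adjusted-p threshold; the direction is derived from the sign
#' of the effect (log2 fold change).
#'
#' @param path Path to the TSV.
#' @param adj_p_threshold Inclusive significance threshold on the adjusted
#'   p (default 0.05).
#' @param columns Named character vector mapping the required fields
#'   (`gene_id`, `effect`, `p`, `adj_p`) to the file's column names.
#' @param directions Length-2 labels for positive / negative effect
#'   (default `up_in_A` / `up_in_B`).
#' @return Data frame with `gene_id`, `effect`, `p`, `adj_p`, `direction`,
#'   `significant`.
#' @export
load_de_results <- function(path, adj_p_threshold = 0.05,
                            columns = c(gene_id = "gene_id",
                                        effect = "log2FoldChange",
                                        p = "pvalue", adj_p = "padj"),
                            directions = c("up_in_A", "up_in_B")) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  miss <- setdiff(unname(columns), colnames(tab))
  if (length(miss))
    stop("DE table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- data.frame(gene_id = as.character(tab[[columns[["gene_id"]]]]),
                    effect = as.numeric(tab[[columns[["effect"]]]]),
                    p = as.numeric(tab[[columns[["p"]]]]),
                    adj_p = as.numeric(tab[[columns[["adj_p"]]]]),
                    stringsAsFactors = FALSE)
  bad <- !is.na(out$p) & (out$p < 0 | out$p > 1)
  if (any(bad))
    stop("p-value outside [0, 1] for gene '", out$gene_id[which(bad)[1]],
         "'", call. = FALSE)
  out$direction <- ifelse(out$effect >= 0, directions[1], directions[2])
  out$significant <- !is.na(out$adj_p) & out$adj_p <= adj_p_threshold
  out
}

#' Built-in two-group differential-expression test
#'
#' Per-gene Welch two-sample t-test on `log2(FPKM + 1)` with
#' Benjamini-Hochberg adjustment; the effect is the difference of group
#' means of `log2(FPKM + 1)` (A minus B). This is deliberately simple
#' plumbing for synthetic end-to-end runs, not a count-model DE method, and
#' the output carries a `method` attribute saying so.
#'
#' @param x FPKM matrix whose columns are the samples of both groups.
#' @param groups Named character vector sample -> `"A"` or `"B"`, or an
#'   unnamed vector aligned with `colnames(x)`.
#' @return Data frame with `gene_id`, `effect`, `p`, `adj_p`, `direction`.
#' @export
simple_de_test <- function(x, groups) {
  validate_expression(x)
  if (!is.null(names(groups))) groups <- groups[colnames(x)]
  groups <- as.character(groups)
  if (length(groups) != ncol(x) || anyNA(groups))
    stop("groups must label every sample", call. = FALSE)
  if (!all(groups %in% c("A", "B")))
    stop("groups must be 'A' or 'B'", call. = FALSE)
  if (sum(groups == "A") < 2L || sum(groups == "B") < 2L)
    stop("need >= 2 samples per group", call. = FALSE)
  lx <- log2(x + 1)
  ia <- groups == "A"; ib <- groups == "B"
  p <- apply(lx, 1L, function(v) {
    if (stats::sd(v[ia]) == 0 && stats::sd(v[ib]) == 0)
      return(if (mean(v[ia]) == mean(v[ib])) 1 else 0)
    stats::t.test(v[ia], v[ib])$p.value
  })
  effect <- rowMeans(lx[, ia, drop = FALSE]) - rowMeans(lx[, ib, drop = FALSE])
  out <- data.frame(gene_id = rownames(x), effect = unname(effect),
                    p = unname(p), adj_p = stats::p.adjust(p, "BH"),
                    direction = ifelse(effect >= 0, "up_in_A", "up_in_B"),
                    stringsAsFactors = FALSE)
  attr(out, "method") <- "welch_t_log2fpkm1_bh"
  out
}

#' Set algebra over gene id sets
#'
#' @param a,b Character vectors of gene ids.
#' @param op `"union"` or `"intersection"`.
#' @return Character vector of gene ids.
#' @export
combine_gene_sets <- function(a, b, op = c("union", "intersection")) {
  op <- match.arg(op)
  if (op == "union") union(a, b) else intersect(a, b)
}

#' Intersect a gene set with a curated annotation list
#'
#' @param genes Gene ids.
#' @param curated Caller-supplied curated gene ids (e.g. a GO-derived list).
#' @return The intersection.
#' @export
intersect_with_annotation_list <- function(genes, curated) {
  intersect(genes, curated)
}
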