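## Relative qPCR quantification: 2^-ddCt and 2^-dCt arithmetic with
## replicate summaries and significance tiers.

#' Relative fold change by the 2^-ddCt method
#'
#' `ddCt = (Ct_target,test - Ct_ref,test) - (Ct_target,cal - Ct_ref,cal)`;
#' the fold change is `2^-ddCt`. Amplification efficiency is fixed at 2
#' (the method's assumption).
#'
#' @param ct_target_test,ct_ref_test Target and reference-gene Ct in the
#'   test sample (cycles).
#' @param ct_target_cal,ct_ref_cal Target and reference-gene Ct in the
#'   calibrator sample.
#' @return Fold change relative to the calibrator.
#' @export
ddct_fold_change <- function(ct_target_test, ct_ref_test,
                             ct_target_cal, ct_ref_cal) {
  stopifnot(is.finite(ct_target_test), is.finite(ct_ref_test),
            is.finite(ct_target_cal), is.finite(ct_ref_cal))
  ddct <- (ct_target_test - ct_ref_test) - (ct_target_cal - ct_ref_cal)
  2^(-ddct)
}

#' Relative expression by the 2^-dCt method
#'
#' @param ct_target Target-gene Ct (cycles).
#' @param ct_ref Reference-gene Ct.
#' @return `2^-(ct_target - ct_ref)`.
#' @export
dct_expression <- function(ct_target, ct_ref) {
  stopifnot(is.finite(ct_target), is.finite(ct_ref))
  2^(-(ct_target - ct_ref))
}

#' Significance tier of a p-value
#'
#' Inclusive boundaries: `p <= 0.001` is `***`, `p <= 0.01` is `**`,
#' `p <= 0.05` is `*`, otherwise `ns`.
#'
#' @param p P-value(s).
#' @return Character tier(s).
#' @export
significance_tier <- function(p) {
  ifelse(p <= 0.001, "***",
         ifelse(p <= 0.01, "**",
                ifelse(p <= 0.05, "*", "ns")))
}

#' Replicate summary with a two-tailed t-test
#'
#' Mean and standard error of the mean per group, a two-tailed two-sample
#' t-test between them (Welch by default), and the significance tier.
#'
#' @param values Replicate measurements for the first group (>= 2).
#' @param other Replicate measurements for the second group (>= 2).
#' @param pooled If `TRUE`, use the equal-variance (pooled) t-test instead
#'   of Welch.
#' @return List with `mean`, `sem` (length-2, one per group), `p`, `tier`.
#' @export
replicate_summary <- function(values, other, pooled = FALSE) {
  if (length(values) < 2L || length(other) < 2L)
    stop("need >= 2 replicates per group", call. = FALSE)
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  p <- if (stats::sd(values) == 0 && stats::sd(other) == 0) {
    if (mean(values) == mean(other)) 1 else 0
  } else {
    stats::t.test(values, other, var.equal = pooled)$p.value
  }
  list(mean = c(mean(values), mean(other)),
       sem = c(sem(values), sem(other)),
       p = p, tier = significance_tier(p))
}

#' Read a Ct replicate table
#'
#' @param path TSV with columns `sample`, `gene`, `replicate`, `Ct`.
#' @return Data frame with those columns; Ct validated finite and > 0.
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample", "gene", "replicate", "Ct")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("Ct table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(tab$Ct) | tab$Ct <= 0))
    stop("Ct values must be finite and > 0", call. = FALSE)
  tab[, need]
}
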