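## Time-course regulator screen: Pearson correlation of candidate
## regulators with a target gene across time points and the exact
## correlation t-test.

#' Exact p-value of a Pearson correlation
#'
#' Two-sided p-value of the test of zero correlation, from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` referred to the t distribution
#' with `n - 2` degrees of freedom (exact t CDF, not a normal
#' approximation). `|r| = 1` returns 0.
#'
#' @param r Correlation in `[-1, 1]` (vectorized).
#' @param n Number of observations, >= 3.
#' @return Two-sided p-value(s) in `[0, 1]`.
#' @export
correlation_pvalue <- function(r, n) {
  if (n < 3) stop("need n >= 3 observations", call. = FALSE)
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("|r| must be <= 1", call. = FALSE)
  r <- pmin(pmax(r, -1), 1)
  p <- rep(0, length(r))
  ok <- abs(r) < 1
  tval <- r[ok] * sqrt(n - 2) / sqrt(1 - r[ok]^2)
  p[ok] <- 2 * stats::pt(-abs(tval), df = n - 2)
  p
}

#' Correlate candidate regulators with a target over a time course
#'
#' Computes the Pearson correlation of each candidate's profile with the
#' target's profile across time points and the exact correlation-test
#' p-value. The target itself is reported with `r = 1`, `p = 0`.
#' Zero-variance candidate profiles are flagged (`r = NA`) and excluded
#' from later classification.
#'
#' @param tc Time-course matrix: gene rows, time-point columns (>= 3).
#' @param target Target gene id, present in `tc`.
#' @param candidates Candidate gene ids, present in `tc`.
#' @return Data frame with `gene_id`, `r`, `p`, `flagged`, sorted by
#'   descending `|r|` (ties by gene id); the target row first.
#' @export
correlate_with_target <- function(tc, target, candidates) {
  if (ncol(tc) < 3L) stop("need >= 3 time points", call. = FALSE)
  miss <- setdiff(c(target, candidates), rownames(tc))
  if (length(miss))
    stop("gene(s) absent from time course: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  y <- tc[target, ]
  if (stats::sd(y) == 0)
    stop("target profile has zero variance", call. = FALSE)
  n <- ncol(tc)
  rows <- lapply(unique(c(target, candidates)), function(g) {
    if (g == target)
      return(data.frame(gene_id = g, r = 1, p = 0, flagged = FALSE,
                        stringsAsFactors = FALSE))
    x <- tc[g, ]
    if (stats::sd(x) == 0)
      return(data.frame(gene_id = g, r = NA_real_, p = NA_real_,
                        flagged = TRUE, stringsAsFactors = FALSE))
    r <- stats::cor(x, y)
    data.frame(gene_id = g, r = r, p = correlation_pvalue(r, n),
               flagged = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rest <- out[out$gene_id != target, , drop = FALSE]
  rest <- rest[order(-abs(rest$r), rest$gene_id, na.last = TRUE), ,
               drop = FALSE]
  out <- rbind(out[out$gene_id == target, , drop = FALSE], rest)
  rownames(out) <- NULL
  out
}

#' Classify regulators by correlation strength
#'
#' Inclusive thresholds: `r >= pos_cut` is `strong_positive`,
#' `r <= neg_cut` is `strong_negative`, everything else (including flagged
#' records with undefined r) is `none`.
#'
#' @param records Data frame with an `r` column (e.g. from
#'   [correlate_with_target()]).
#' @param pos_cut Positive cut (default 0.95).
#' @param neg_cut Negative cut (default -0.95).
#' @return `records` with a `class` column added.
#' @export
classify_regulators <- function(records, pos_cut = 0.95, neg_cut = -0.95) {
  cls <- rep("none", nrow(records))
  cls[!is.na(records$r) & records$r >= pos_cut] <- "strong_positive"
  cls[!is.na(records$r) & records$r <= neg_cut] <- "strong_negative"
  records$class <- cls
  records
}

#' Read a time-course TSV
#'
#' Gene rows, columns labelled by hour; enforces >= 3 strictly increasing
#' time points.
#'
#' @param path Path to the TSV (first column gene ids, header of hours).
#' @param transform Optional `function(x)` applied elementwise (e.g.
#'   `function(x) log2(x + 1)`); default identity.
#' @return Numeric matrix with a `hours` attribute.
#' @export
read_timecourse <- function(path, transform = identity) {
  m <- read_expression_table(path)
  hours <- suppressWarnings(as.numeric(colnames(m)))
  if (anyNA(hours) || length(hours) < 3L || is.unsorted(hours, strictly = TRUE))
    stop("time-course columns must be >= 3 strictly increasing hours",
         call. = FALSE)
  m <- transform(m)
  attr(m, "hours") <- hours
  m
}
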