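## Expression-matrix ingestion, validation and elementwise transforms.
##
## An expression matrix is represented as a plain numeric matrix of
## nonnegative FPKM values with gene ids as rownames and sample ids as
## colnames; all functions validate this contract at the boundary.

#' Validate an FPKM expression matrix
#'
#' Checks the container contract used throughout the package: a numeric
#' matrix with unique, non-empty gene rownames and sample colnames, and all
#' values finite and nonnegative.
#'
#' @param x Numeric matrix, genes in rows, samples in columns.
#' @param what Label used in error messages.
#' @return `x`, invisibly, if valid; otherwise an error is thrown naming the
#'   offending gene/sample.
#' @export
validate_expression <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (nrow(x) == 0L || ncol(x) == 0L)
    stop(what, " is empty", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " must carry gene rownames and sample colnames", call. = FALSE)
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup))
    stop("duplicated gene id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  dup <- colnames(x)[duplicated(colnames(x))]
  if (length(dup))
    stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(x) | x < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite or negative value at gene '", rownames(x)[bad[1, 1]],
         "', sample '", colnames(x)[bad[1, 2]], "'", call. = FALSE)
  invisible(x)
}

#' Read a gene-by-sample FPKM table
#'
#' Reads a tab-separated table whose first column holds gene identifiers and
#' whose header row holds sample identifiers, and returns a validated
#' numeric matrix.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix with genes in rows (input order preserved) and
#'   samples in columns.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("expression table needs a gene-id column plus >= 1 sample column",
         call. = FALSE)
  ids <- as.character(tab[[1L]])
  vals <- tab[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1L]
      stop("non-numeric value in column '", colnames(vals)[j], "'",
           if (!is.na(bad)) paste0(", row '", ids[bad], "'"), call. = FALSE)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  validate_expression(m)
  m
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_table()]: first column `gene_id`, one column
#' per sample, values formatted with `%.17g` (full double precision) so a
#' write/read round trip is bit-identical.
#'
#' @param x Expression matrix.
#' @param path Output file path.
#' @param comment Optional character vector written as leading `#` lines.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c("gene_id", colnames(x)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(x)), function(i)
    paste(c(rownames(x)[i], sprintf("%.17g", x[i, ])), collapse = "\t"),
    character(1))
  writeLines(body, con)
  invisible(path)
}

#' Filter to expressed genes
#'
#' A gene is considered expressed when its FPKM is at least `min_value` in at
#' least `min_fraction` of the samples; both comparisons are inclusive, so a
#' gene at FPKM exactly 0.1 in exactly 25% of samples is retained under the
#' defaults.
#'
#' @param x FPKM matrix.
#' @param min_value Abundance threshold (default 0.1 FPKM).
#' @param min_fraction Minimum fraction of samples at or above `min_value`
#'   (default 0.25).
#' @return List with `matrix` (the retained rows) and `kept` (named logical
#'   mask over the input genes).
#' @export
filter_expressed <- function(x, min_value = 0.1, min_fraction = 0.25) {
  validate_expression(x)
  if (!(min_fraction > 0 && min_fraction <= 1))
    stop("min_fraction must be in (0, 1]", call. = FALSE)
  frac <- rowMeans(x >= min_value)
  kept <- frac >= min_fraction
  names(kept) <- rownames(x)
  list(matrix = x[kept, , drop = FALSE], kept = kept)
}

#' Restrict an expression matrix to selected biotypes
#'
#' @param x Expression matrix.
#' @param annotation Gene annotation data frame (see [read_gene_annotation()]).
#' @param keep Biotypes to retain (default lncRNA and mRNA).
#' @param strict If `TRUE` (default), a matrix gene absent from the
#'   annotation is an error; otherwise such genes are dropped with a warning.
#' @return Expression matrix restricted to annotated genes of the kept
#'   biotypes, input order preserved.
#' @export
restrict_biotypes <- function(x, annotation, keep = c("lncRNA", "mRNA"),
                              strict = TRUE) {
  validate_expression(x)
  stopifnot(all(keep %in% c("lncRNA", "mRNA", "other")))
  bt <- stats::setNames(annotation$biotype, annotation$gene_id)
  missing <- setdiff(rownames(x), names(bt))
  if (length(missing)) {
    if (strict)
      stop("gene(s) missing from annotation: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    warning(length(missing), " unannotated gene(s) dropped")
  }
  sel <- rownames(x) %in% names(bt)[bt %in% keep]
  x[sel, , drop = FALSE]
}

#' log(FPKM + 1) transform
#'
#' @param x FPKM matrix (values >= 0).
#' @param base Logarithm base, default 2. Downstream correlation-based
#'   results are invariant to the base (the transform differs only by a
#'   positive scale factor).
#' @return Matrix of `log_base(x + 1)` values; attribute `log_base` records
#'   the base used.
#' @export
log_transform <- function(x, base = 2) {
  validate_expression(x)
  if (!is.numeric(base) || base <= 0 || base == 1)
    stop("base must be positive and != 1", call. = FALSE)
  out <- log(x + 1, base = base)
  attr(out, "log_base") <- base
  out
}

#' Per-gene maximum normalization
#'
#' Divides each gene's values by that gene's row maximum so the per-gene
#' maximum becomes 1 (the presentation convention for cross-cell-type
#' expression profiles). All-zero rows pass through unchanged and are
#' reported in the `flagged` attribute.
#'
#' @param x Expression matrix.
#' @return Normalized matrix; attribute `flagged` lists all-zero gene ids.
#' @export
max_normalize_per_gene <- function(x) {
  validate_expression(x)
  mx <- apply(x, 1L, max)
  zero <- mx == 0
  scl <- ifelse(zero, 1, mx)
  out <- x / scl
  attr(out, "flagged") <- rownames(x)[zero]
  out
}
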