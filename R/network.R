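## Signed weighted co-expression network: correlation, soft-thresholded
## adjacency, scale-free topology fit, topological overlap, connectivity.
##
## All matrices are dense, symmetric, indexed by the same gene order.
## Diagonals of adjacency and TOM are fixed at 1 by convention; every
## connectivity sum excludes the self term.

#' Pearson correlation matrix across samples
#'
#' @param logmat Log-expression matrix (genes x samples), >= 3 samples.
#' @param strict If `TRUE` (default) a zero-variance gene is an error;
#'   otherwise such genes are dropped with a warning.
#' @return Symmetric gene x gene correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(logmat, strict = TRUE) {
  if (ncol(logmat) < 3L)
    stop("need >= 3 samples for correlation", call. = FALSE)
  v <- apply(logmat, 1L, stats::var)
  flat <- v <= 0 | !is.finite(v)
  if (any(flat)) {
    if (strict)
      stop("zero-variance gene(s): ",
           paste(utils::head(rownames(logmat)[flat], 5), collapse = ", "),
           call. = FALSE)
    warning(sum(flat), " zero-variance gene(s) dropped")
    logmat <- logmat[!flat, , drop = FALSE]
  }
  cc <- stats::cor(t(logmat))
  cc[cc > 1] <- 1
  cc[cc < -1] <- -1
  diag(cc) <- 1
  cc
}

#' Signed soft-thresholded adjacency
#'
#' The signed adjacency `a_ij = ((1 + cor_ij) / 2)^beta` maps correlation
#' -1 to 0 and +1 to 1, so negatively correlated genes are treated as
#' unconnected rather than connected.
#'
#' @param cor Correlation matrix.
#' @param beta Soft power, integer >= 1.
#' @return Adjacency matrix in `[0, 1]` with unit diagonal; attribute
#'   `beta` records the power.
#' @export
signed_adjacency <- function(cor, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || beta < 1)
    stop("beta must be a single number >= 1", call. = FALSE)
  a <- ((1 + cor) / 2)^beta
  diag(a) <- 1
  attr(a, "beta") <- beta
  a
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins connectivity into `n_bins` equal-width bins and regresses
#' `log10(mean frequency)` on `log10(mean connectivity)` over the nonempty
#' bins with positive mean connectivity. The fit index is the regression R^2
#' signed by `-slope`, so a decreasing (scale-free-like) degree distribution
#' scores positively.
#'
#' @param k Nonnegative connectivity vector.
#' @param n_bins Number of equal-width bins (default 10).
#' @return List with `fit_index`, `slope`, `r_squared`, `n_bins_used`.
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  if (any(k < 0)) stop("connectivity must be nonnegative", call. = FALSE)
  brk <- seq(min(k), max(k), length.out = n_bins + 1L)
  if (length(unique(brk)) < 3L)
    stop("degenerate degree distribution", call. = FALSE)
  bin <- cut(k, breaks = brk, include.lowest = TRUE)
  mean_k <- tapply(k, bin, mean)
  freq <- as.numeric(table(bin)) / length(k)
  use <- !is.na(mean_k) & freq > 0 & mean_k > 0
  if (sum(use) < 2L)
    stop("degenerate degree distribution", call. = FALSE)
  fit <- stats::lm(log10(freq[use]) ~ log10(mean_k[use]))
  r2 <- summary(fit)$r.squared
  slope <- unname(stats::coef(fit)[2L])
  list(fit_index = r2 * sign(-slope), slope = slope, r_squared = r2,
       n_bins_used = sum(use))
}

#' Choose the soft power by scale-free topology fit
#'
#' For each candidate power the signed adjacency and whole-network
#' connectivity are computed and the scale-free fit evaluated; the returned
#' power is the smallest whose fit index reaches `fit_cut`. If none
#' qualifies, the power with the maximal fit index is returned with
#' `warning_flag = TRUE`.
#'
#' @param logmat Log-expression matrix.
#' @param powers Ascending integer powers to scan (default 1:25).
#' @param fit_cut Fit-index cut (default 0.8).
#' @param n_bins Bins for [scale_free_fit()].
#' @return List with `beta`, `fits` (per-power data frame of
#'   `power`, `fit_index`, `slope`, `mean_k`), and `warning_flag`.
#' @export
pick_soft_threshold <- function(logmat, powers = 1:25, fit_cut = 0.8,
                                n_bins = 10) {
  if (!length(powers) || is.unsorted(powers))
    stop("powers must be nonempty and ascending", call. = FALSE)
  cc <- correlation_matrix(logmat)
  base <- (1 + cc) / 2
  diag(base) <- 0          # self excluded from connectivity
  fits <- data.frame(power = powers, fit_index = NA_real_,
                     slope = NA_real_, mean_k = NA_real_)
  for (i in seq_along(powers)) {
    k <- rowSums(base^powers[i])
    fits$mean_k[i] <- mean(k)
    sf <- tryCatch(scale_free_fit(k, n_bins = n_bins),
                   error = function(e) NULL)
    if (!is.null(sf)) {
      fits$fit_index[i] <- sf$fit_index
      fits$slope[i] <- sf$slope
    }
  }
  ok <- which(!is.na(fits$fit_index) & fits$fit_index >= fit_cut)
  if (length(ok)) {
    list(beta = powers[ok[1L]], fits = fits, warning_flag = FALSE)
  } else {
    if (all(is.na(fits$fit_index)))
      stop("no usable scale-free fit at any power", call. = FALSE)
    best <- which.max(fits$fit_index)
    warning("no power reached fit_cut = ", fit_cut,
            "; falling back to the best-fitting power ", powers[best])
    list(beta = powers[best], fits = fits, warning_flag = TRUE)
  }
}

#' Topological overlap matrix
#'
#' For genes i != j,
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `L_ij = sum_{u != i,j} a_iu a_uj` counts shared neighbourhood and
#' `k_i = sum_{u != i} a_iu` is connectivity; the diagonal is 1.
#'
#' @param adj Adjacency matrix.
#' @return TOM matrix in `[0, 1]`, symmetric, unit diagonal.
#' @export
topological_overlap <- function(adj) {
  a <- adj
  diag(a) <- 0
  L <- a %*% a                     # L_ij = sum_u a_iu a_uj, u != i,j since diag 0
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (L + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' TOM dissimilarity
#'
#' @param tom TOM matrix.
#' @return `1 - tom`, zero diagonal.
#' @export
diss_tom <- function(tom) {
  d <- 1 - tom
  diag(d) <- 0
  d
}

#' Whole-network and intramodular connectivity
#'
#' Whole-network connectivity of gene i is the sum of its adjacency weights
#' to all other genes; when a module assignment is supplied, intramodular
#' connectivity (kIM) restricts the sum to same-module genes.
#'
#' @param adj Adjacency matrix.
#' @param assignment Optional named module-label vector covering all genes.
#' @return Named vector `k`, or when `assignment` is given a data frame
#'   with columns `gene_id`, `module`, `k`, `kim`.
#' @export
connectivity <- function(adj, assignment = NULL) {
  a <- adj
  diag(a) <- 0
  k <- rowSums(a)
  if (is.null(assignment)) return(k)
  genes <- rownames(adj)
  if (!all(genes %in% names(assignment)))
    stop("assignment must cover all genes in the adjacency", call. = FALSE)
  mod <- assignment[genes]
  kim <- numeric(length(genes))
  for (m in unique(mod)) {
    idx <- which(mod == m)
    kim[idx] <- rowSums(a[idx, idx, drop = FALSE])
  }
  data.frame(gene_id = genes, module = unname(mod), k = unname(k),
             kim = kim, stringsAsFactors = FALSE)
}

#' Module-scaled intramodular degree
#'
#' Within each module the intramodular connectivity is divided by the module
#' maximum, so every module's best-connected gene scores exactly 1. Genes in
#' the grey (unassigned) group score `NA`.
#'
#' @param kim Named numeric vector of intramodular connectivity.
#' @param assignment Named module-label vector over the same genes.
#' @param grey_label Label of the unassigned group (default `"grey"`).
#' @return Named numeric vector of scaled degrees in `[0, 1]` (NA for grey).
#' @export
scaled_intramodular_degree <- function(kim, assignment, grey_label = "grey") {
  stopifnot(!is.null(names(kim)), all(names(kim) %in% names(assignment)))
  mod <- assignment[names(kim)]
  out <- rep(NA_real_, length(kim))
  names(out) <- names(kim)
  for (m in setdiff(unique(mod), grey_label)) {
    idx <- which(mod == m)
    mx <- max(kim[idx])
    if (mx <= 0) {
      warning("module '", m, "' has zero maximal intramodular connectivity")
      out[idx] <- 0
    } else {
      out[idx] <- kim[idx] / mx
    }
  }
  out
}

#' Write a symmetric gene x gene matrix as TSV
#'
#' Gene ids appear both as the header and the first column; values use the
#' `%.10g` format.
#'
#' @param m Matrix with gene dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_matrix <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(m)), collapse = "\t"), con)
  writeLines(vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], sprintf("%.10g", m[i, ])), collapse = "\t"),
    character(1)), con)
  invisible(path)
}
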