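## The network/module estimator: one fitting function returning a classed
## object, in the classic R modelling idiom.

#' Fit a signed weighted co-expression network and detect modules
#'
#' Runs the full network stage on an FPKM matrix: expression filtering,
#' optional biotype restriction, `log(FPKM + 1)` transform, soft-power
#' selection by scale-free topology fit (unless `beta` is given), signed
#' adjacency, topological overlap, average-linkage clustering of
#' `1 - TOM`, tree-variant dynamic cut, eigengene merging of correlated
#' modules, and per-gene (intra)modular connectivity.
#'
#' @param x FPKM matrix (genes x samples).
#' @param annotation Optional gene annotation; when given, genes are
#'   restricted to `keep_biotypes` before the network is built.
#' @param min_value,min_fraction Expression filter: FPKM at least
#'   `min_value` in at least `min_fraction` of samples (defaults 0.1, 0.25).
#' @param keep_biotypes Biotypes kept when `annotation` is given.
#' @param log_base Base of the `log(FPKM + 1)` transform (default 2; all
#'   correlation-based results are invariant to it).
#' @param powers,fit_cut Soft powers scanned and the scale-free fit cut
#'   (defaults 1:25 and 0.8).
#' @param beta Optional fixed soft power, skipping the scan.
#' @param min_module_size,cut_height_fraction,gap_fraction Dynamic-cut
#'   parameters (see [dynamic_tree_cut()]).
#' @param merge_cor Eigengene correlation at or above which modules merge
#'   (default 0.85).
#' @return Object of class `coexp_fit` with components `assignment`
#'   (merged, size-ranked labels plus `"grey"`), `assignment_initial`,
#'   `connectivity` (data frame `gene_id`, `module`, `k`, `kim`,
#'   `scaled_degree`), `beta`, `power_fits`, `dendrogram`, `eigengenes`,
#'   `logmat`, `kept`, `params`, `call`.
#' @seealso [essential_screen()], [print.coexp_fit()], [plot.coexp_fit()]
#' @export
#' @examples
#' sim <- simulate_modular_expression(
#'   sim_config(module_sizes = c(40, 35), n_noise_genes = 10, seed = 7))
#' fit <- coexp_fit(sim$matrix, sim$annotation, min_module_size = 20,
#'                  powers = 1:12)
#' fit
coexp_fit <- function(x, annotation = NULL,
                      min_value = 0.1, min_fraction = 0.25,
                      keep_biotypes = c("lncRNA", "mRNA"),
                      log_base = 2,
                      powers = 1:25, fit_cut = 0.8, beta = NULL,
                      min_module_size = 30, cut_height_fraction = 0.99,
                      gap_fraction = 0.1, merge_cor = 0.85) {
  cl <- match.call()
  flt <- filter_expressed(x, min_value, min_fraction)
  m <- flt$matrix
  if (!is.null(annotation))
    m <- restrict_biotypes(m, annotation, keep = keep_biotypes)
  if (nrow(m) < 3L)
    stop("fewer than 3 genes survive filtering", call. = FALSE)
  logmat <- log_transform(m, base = log_base)

  if (is.null(beta)) {
    sel <- pick_soft_threshold(logmat, powers = powers, fit_cut = fit_cut)
    beta <- sel$beta
    power_fits <- sel$fits
    beta_warning <- sel$warning_flag
  } else {
    power_fits <- NULL
    beta_warning <- FALSE
  }

  cc <- correlation_matrix(logmat)
  adj <- signed_adjacency(cc, beta)
  tom <- topological_overlap(adj)
  dendro <- hierarchical_cluster(diss_tom(tom))
  asg0 <- dynamic_tree_cut(dendro, min_module_size = min_module_size,
                           cut_height_fraction = cut_height_fraction,
                           gap_fraction = gap_fraction)
  asg <- if (any(asg0 != "grey"))
    merge_modules(logmat, asg0, cor_threshold = merge_cor) else asg0
  conn <- connectivity(adj, asg)
  kim <- stats::setNames(conn$kim, conn$gene_id)
  conn$scaled_degree <- unname(
    scaled_intramodular_degree(kim, asg)[conn$gene_id])
  eg <- if (any(asg != "grey")) module_eigengenes(logmat, asg) else NULL

  structure(list(
    assignment = asg, assignment_initial = asg0, connectivity = conn,
    beta = beta, beta_warning = beta_warning, power_fits = power_fits,
    dendrogram = dendro, eigengenes = eg, logmat = logmat,
    kept = flt$kept,
    params = list(min_value = min_value, min_fraction = min_fraction,
                  log_base = log_base, fit_cut = fit_cut,
                  min_module_size = min_module_size,
                  cut_height_fraction = cut_height_fraction,
                  gap_fraction = gap_fraction, merge_cor = merge_cor),
    call = cl), class = "coexp_fit")
}

#' @export
print.coexp_fit <- function(x, ...) {
  sizes <- module_sizes(x)
  cat("Signed co-expression network fit\n")
  cat("  genes:", length(x$assignment),
      " samples:", ncol(x$logmat), "\n")
  cat("  soft power:", x$beta,
      if (isTRUE(x$beta_warning)) "(fit cut not reached)" else "", "\n")
  cat("  modules:", length(sizes),
      " grey genes:", sum(x$assignment == "grey"), "\n")
  invisible(x)
}

#' Module sizes of a network fit
#'
#' @param fit A `coexp_fit`.
#' @param grey_label Unassigned label.
#' @return Named integer vector of non-grey module sizes, largest first.
#' @export
module_sizes <- function(fit, grey_label = "grey") {
  tab <- table(fit$assignment)
  tab <- tab[setdiff(names(tab), grey_label)]
  sizes <- sort(as.integer(tab), decreasing = TRUE)
  names(sizes) <- names(tab)[order(-as.integer(tab))]
  sizes
}

#' @export
summary.coexp_fit <- function(object, ...) {
  sizes <- module_sizes(object)
  ve <- if (!is.null(object$eigengenes)) {
    vapply(colnames(object$eigengenes), function(m)
      module_eigengene(object$logmat,
                       names(object$assignment)[object$assignment == m]
                       )$variance_explained, numeric(1))
  } else numeric(0)
  out <- list(n_genes = length(object$assignment),
              n_samples = ncol(object$logmat),
              beta = object$beta, beta_warning = object$beta_warning,
              module_sizes = sizes,
              n_grey = sum(object$assignment == "grey"),
              variance_explained = ve)
  class(out) <- "summary.coexp_fit"
  out
}

#' @export
print.summary.coexp_fit <- function(x, ...) {
  cat("Signed co-expression network fit\n")
  cat("  genes:", x$n_genes, " samples:", x$n_samples, "\n")
  cat("  soft power:", x$beta,
      if (isTRUE(x$beta_warning)) "(fit cut not reached)" else "", "\n")
  cat("  grey genes:", x$n_grey, "\n  modules:\n")
  for (m in names(x$module_sizes))
    cat(sprintf("    %-6s %5d genes  eigengene var. explained %.2f\n",
                m, x$module_sizes[m],
                x$variance_explained[m]))
  invisible(x)
}

#' Per-gene coefficients of a network fit
#'
#' @param object A `coexp_fit`.
#' @param ... Unused.
#' @return Data frame with `gene_id`, `module`, `k`, `kim`,
#'   `scaled_degree`.
#' @export
coef.coexp_fit <- function(object, ...) object$connectivity

#' Plot a network fit
#'
#' Left: the gene dendrogram with module labels along the leaves; right:
#' the scale-free fit index per candidate soft power (when the power scan
#' was run) with the selected power marked.
#'
#' @param x A `coexp_fit`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.coexp_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, if (is.null(x$power_fits)) 1 else 2))
  on.exit(graphics::par(op))
  graphics::plot(x$dendrogram, labels = FALSE, hang = -1,
                 main = "TOM dissimilarity dendrogram",
                 xlab = "", sub = "", ...)
  if (!is.null(x$power_fits)) {
    graphics::plot(x$power_fits$power, x$power_fits$fit_index, type = "b",
                   xlab = "soft power", ylab = "scale-free fit index",
                   main = "Soft-threshold selection")
    graphics::abline(h = x$params$fit_cut, lty = 2)
    graphics::abline(v = x$beta, col = 2, lty = 3)
  }
  invisible(x)
}
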