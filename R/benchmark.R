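## Module-recovery benchmark: run the default pipeline on simulated data
## with planted modules and score recovery against the generator truth.

#' Adjusted Rand index of recovered modules against planted truth
#'
#' Scores the recovered non-grey assignment: genes the pipeline assigned to
#' a module are compared with their planted module labels (genes planted as
#' unassignable noise carry the label `"none"`, so adopting noise genes
#' into a module counts against recovery). Grey genes are excluded — they
#' are the pipeline's explicit "no call".
#'
#' @param assignment Named recovered module-label vector.
#' @param truth Truth data frame with `gene_id` and `module` (`NA` for
#'   noise genes), as emitted by [simulate_modular_expression()].
#' @param grey_label Unassigned label.
#' @return Adjusted Rand index (requires the mclust package).
#' @export
recovery_ari <- function(assignment, truth, grey_label = "grey") {
  if (!requireNamespace("mclust", quietly = TRUE))
    stop("recovery_ari requires the mclust package", call. = FALSE)
  asg <- assignment[truth$gene_id]
  keep <- !is.na(asg) & asg != grey_label
  planted <- ifelse(is.na(truth$module), "none", truth$module)
  mclust::adjustedRandIndex(asg[keep], planted[keep])
}

#' Run the module-recovery benchmark over several seeds
#'
#' For each seed, simulates the default planted-module data set (or the
#' given configuration), runs the default network/module pipeline, and
#' reports the selected power, module and grey counts, the recovery ARI
#' ([recovery_ari()]) and the maximal post-merge eigengene correlation.
#'
#' @param seeds Integer seeds (default 1:10).
#' @param config_for Function seed -> [sim_config()] (default: generator
#'   defaults at that seed).
#' @param ... Passed to [coexp_fit()].
#' @return Data frame, one row per seed: `seed`, `beta`, `beta_warning`,
#'   `n_modules`, `n_grey`, `ari`, `max_eigengene_cor`.
#' @export
module_recovery_benchmark <- function(seeds = 1:10,
                                      config_for = function(s)
                                        sim_config(seed = s),
                                      ...) {
  rows <- lapply(seeds, function(s) {
    sim <- simulate_modular_expression(config_for(s))
    fit <- suppressWarnings(coexp_fit(sim$matrix, sim$annotation, ...))
    max_eg <- if (!is.null(fit$eigengenes) && ncol(fit$eigengenes) > 1L) {
      cc <- stats::cor(fit$eigengenes)
      max(cc[upper.tri(cc)])
    } else -Inf
    data.frame(seed = s, beta = fit$beta,
               beta_warning = fit$beta_warning,
               n_modules = length(module_sizes(fit)),
               n_grey = sum(fit$assignment == "grey"),
               ari = recovery_ari(fit$assignment, sim$truth),
               max_eigengene_cor = max_eg)
  })
  do.call(rbind, rows)
}
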