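## Synthetic-data generators with planted ground truth: modular expression
## matrices, two-condition differential expression, and time courses with
## exactly realized regulator-target correlations.

#' Simulation configuration for modular expression data
#'
#' Defaults describe the package's standard benchmark: five planted
#' co-expression modules of sizes 120/90/70/50/30 over 20 samples, per-gene
#' loadings drawn from `[0.6, 0.9]` with one hub per module pinned at the
#' loading maximum, 40 unassignable noise genes, a 19% lncRNA biotype
#' fraction, and log-scale Gaussian noise with sd 0.5.
#'
#' @param n_samples Number of samples.
#' @param module_sizes Integer vector of planted module sizes.
#' @param loading_range Range `[lo, hi]` in `(0, 1]` for per-gene loadings.
#' @param n_hubs_per_module Hubs per module (loading pinned at `hi`).
#' @param n_noise_genes Independent (unassignable) genes.
#' @param lncRNA_fraction Fraction of genes labelled lncRNA.
#' @param noise_sd Log2-scale Gaussian noise sd.
#' @param baseline_range Range of per-gene baseline log2 expression.
#' @param seed Mandatory integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_samples = 20,
                       module_sizes = c(120, 90, 70, 50, 30),
                       loading_range = c(0.6, 0.9),
                       n_hubs_per_module = 1,
                       n_noise_genes = 40,
                       lncRNA_fraction = 0.19,
                       noise_sd = 0.5,
                       baseline_range = c(2, 6),
                       seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(all(module_sizes >= 1),
            loading_range[1] > 0, loading_range[2] <= 1,
            loading_range[1] <= loading_range[2],
            lncRNA_fraction >= 0, lncRNA_fraction <= 1,
            noise_sd >= 0, n_samples >= 3)
  if (any(n_hubs_per_module > module_sizes))
    stop("hub count exceeds a module size", call. = FALSE)
  structure(list(n_samples = n_samples, module_sizes = module_sizes,
                 loading_range = loading_range,
                 n_hubs_per_module = n_hubs_per_module,
                 n_noise_genes = n_noise_genes,
                 lncRNA_fraction = lncRNA_fraction, noise_sd = noise_sd,
                 baseline_range = baseline_range, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an FPKM matrix with planted co-expression modules
#'
#' Each module m draws a per-sample profile `e_m ~ N(0, 1)`; a member gene g
#' has log2 expression `mu_g + lambda_g * e_m + eps`,
#' `eps ~ N(0, noise_sd)`, with loading `lambda_g` uniform on the module's
#' loading range and designated hub genes pinned at the range maximum.
#' Noise genes are independent `mu_g + N(0, 1)`. The log2 values are
#' back-transformed to the FPKM scale as `max(2^x - 1, 0)` so the
#' expression filter's semantics stay meaningful. Biotypes are assigned at
#' `lncRNA_fraction`; everything is deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @return List with `matrix` (FPKM), `annotation` (gene annotation data
#'   frame), and `truth` (data frame: `gene_id`, `module` — `NA` for noise
#'   genes —, `biotype`, `is_hub`, `loading`).
#' @export
simulate_modular_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_mod_genes <- sum(config$module_sizes)
  n_genes <- n_mod_genes + config$n_noise_genes
  ids <- sprintf("G%05d", seq_len(n_genes))
  module <- c(rep(paste0("true", seq_along(config$module_sizes)),
                  config$module_sizes),
              rep(NA_character_, config$n_noise_genes))
  loading <- rep(NA_real_, n_genes)
  is_hub <- rep(FALSE, n_genes)
  lo <- config$loading_range[1]; hi <- config$loading_range[2]
  offset <- 0L
  profiles <- matrix(stats::rnorm(length(config$module_sizes) *
                                    config$n_samples),
                     nrow = length(config$module_sizes))
  logx <- matrix(0, n_genes, config$n_samples)
  mu <- stats::runif(n_genes, config$baseline_range[1],
                     config$baseline_range[2])
  for (m in seq_along(config$module_sizes)) {
    sz <- config$module_sizes[m]
    idx <- offset + seq_len(sz)
    lam <- stats::runif(sz, lo, hi)
    lam[seq_len(config$n_hubs_per_module)] <- hi
    is_hub[idx[seq_len(config$n_hubs_per_module)]] <- TRUE
    loading[idx] <- lam
    logx[idx, ] <- mu[idx] + outer(lam, profiles[m, ]) +
      matrix(stats::rnorm(sz * config$n_samples, sd = config$noise_sd),
             nrow = sz)
    offset <- offset + sz
  }
  if (config$n_noise_genes > 0) {
    idx <- n_mod_genes + seq_len(config$n_noise_genes)
    logx[idx, ] <- mu[idx] +
      matrix(stats::rnorm(config$n_noise_genes * config$n_samples),
             nrow = config$n_noise_genes)
  }
  fpkm <- pmax(2^logx - 1, 0)
  rownames(fpkm) <- ids
  colnames(fpkm) <- sprintf("S%02d", seq_len(config$n_samples))
  biotype <- ifelse(stats::runif(n_genes) < config$lncRNA_fraction,
                    "lncRNA", "mRNA")
  annotation <- data.frame(
    gene_id = ids, symbol = ids, biotype = biotype,
    chromosome = paste0("chr", sample(1:19, n_genes, replace = TRUE)),
    stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = ids, module = module, biotype = biotype,
                      is_hub = is_hub, loading = loading,
                      stringsAsFactors = FALSE)
  list(matrix = fpkm, annotation = annotation, truth = truth)
}

#' Simulate a time course with exactly realized correlations
#'
#' For each requested regulator with target correlation `rho`, the profile
#' is built as `rho * z + sqrt(1 - rho^2) * w`, where `z` is the
#' standardized target profile and `w` a standardized residual orthogonal
#' to `z` and the constant, so the realized Pearson correlation with the
#' target equals `rho` exactly (constructive, not sampled). Profiles are
#' affinely shifted to a positive synthesis-rate-like scale, which leaves
#' Pearson correlations unchanged.
#'
#' @param time_points Strictly increasing vector of >= 3 hours.
#' @param target_profile Target values at the time points (non-constant).
#' @param regulator_cors Named vector regulator id -> requested correlation
#'   in `[-1, 1]`.
#' @param target_id Row label for the target (default `"target"`).
#' @param seed Integer seed.
#' @return List with `tc` (gene x time matrix including the target row,
#'   `hours` attribute) and `truth` (the requested correlations).
#' @export
simulate_timecourse <- function(time_points, target_profile, regulator_cors,
                                target_id = "target", seed) {
  if (length(time_points) < 3L)
    stop("need >= 3 time points", call. = FALSE)
  if (is.unsorted(time_points, strictly = TRUE))
    stop("time points must be strictly increasing", call. = FALSE)
  stopifnot(length(target_profile) == length(time_points),
            all(abs(regulator_cors) <= 1))
  if (stats::sd(target_profile) == 0)
    stop("target profile must be non-constant", call. = FALSE)
  set.seed(seed)
  nt <- length(time_points)
  z <- as.numeric(scale(target_profile))    # mean 0, sd 1
  mk_resid <- function() {
    repeat {
      w <- stats::rnorm(nt)
      w <- w - mean(w)
      w <- w - sum(w * z) / sum(z * z) * z
      if (stats::sd(w) > 1e-10) return(w / stats::sd(w))
    }
  }
  prof <- t(vapply(regulator_cors, function(rho)
    10 + 2 * (rho * z + sqrt(1 - rho^2) * mk_resid()), numeric(nt)))
  tc <- rbind(matrix(target_profile, nrow = 1), prof)
  rownames(tc) <- c(target_id, names(regulator_cors))
  colnames(tc) <- as.character(time_points)
  attr(tc, "hours") <- time_points
  list(tc = tc, truth = regulator_cors)
}

#' Simulate a two-condition differential-expression experiment
#'
#' Both conditions share each gene's baseline (the mean `log2(FPKM + 1)` of
#' the input matrix); condition B shifts the planted genes by the stated
#' log2 effect. Fresh Gaussian noise is added per sample in both
#' conditions; back-transform is `max(2^x - 1, 0)`. Deterministic given the
#' seed.
#'
#' @param x Baseline FPKM matrix (genes define the universe).
#' @param de_genes Gene ids receiving the effect (subset of `rownames(x)`).
#' @param effect Log2 effect added in condition B (default 2, a 4-fold
#'   change).
#' @param n_per_group Samples per condition (default 10).
#' @param noise_sd Log2-scale noise sd (default 0.3).
#' @param seed Integer seed.
#' @return List with `A`, `B` (FPKM matrices), `de_genes`, `effect`.
#' @export
simulate_de <- function(x, de_genes = character(), effect = 2,
                        n_per_group = 10, noise_sd = 0.3, seed) {
  validate_expression(x)
  bad <- setdiff(de_genes, rownames(x))
  if (length(bad))
    stop("de genes absent from matrix: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  set.seed(seed)
  mu <- rowMeans(log2(x + 1))
  n <- nrow(x)
  noise <- function() matrix(stats::rnorm(n * n_per_group, sd = noise_sd),
                             nrow = n)
  la <- mu + noise()
  lb <- mu + noise()
  lb[rownames(x) %in% de_genes, ] <- lb[rownames(x) %in% de_genes, ] + effect
  mk <- function(lx, tag) {
    f <- pmax(2^lx - 1, 0)
    rownames(f) <- rownames(x)
    colnames(f) <- sprintf("%s%02d", tag, seq_len(n_per_group))
    f
  }
  list(A = mk(la, "A"), B = mk(lb, "B"), de_genes = de_genes,
       effect = effect)
}
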