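## Essentiality screen: top intramodular-degree genes per module, biotype
## and chromosome bookkeeping, DE overlap, Fisher enrichment.

#' Essential genes: top intramodular degree per module
#'
#' Within each non-grey module, the `ceiling(top_fraction * size)` genes
#' with the highest intramodular connectivity are called essential. Ties are
#' broken by higher scaled degree then lexicographic gene id. Grey genes are
#' never eligible.
#'
#' @param assignment Named module-label vector.
#' @param kim Named intramodular-connectivity vector over the same genes.
#' @param top_fraction Fraction selected per module (default 0.25).
#' @param grey_label Unassigned label.
#' @return Data frame with `gene_id`, `module`, `kim`, `scaled_degree`,
#'   ordered by module then descending connectivity.
#' @export
essential_genes <- function(assignment, kim, top_fraction = 0.25,
                            grey_label = "grey") {
  stopifnot(!is.null(names(kim)))
  nz <- names(assignment)[assignment != grey_label]
  if (!all(nz %in% names(kim)))
    stop("kim must be defined for every non-grey gene", call. = FALSE)
  scaled <- scaled_intramodular_degree(kim, assignment, grey_label)
  out <- list()
  for (m in setdiff(sort(unique(assignment)), grey_label)) {
    ids <- names(assignment)[assignment == m]
    n_take <- ceiling(top_fraction * length(ids))
    ord <- ids[order(-kim[ids], -scaled[ids], ids)]
    take <- ord[seq_len(n_take)]
    out[[m]] <- data.frame(gene_id = take, module = m,
                           kim = unname(kim[take]),
                           scaled_degree = unname(scaled[take]),
                           stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene_id = character(), module = character(),
                      kim = numeric(), scaled_degree = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Biotype composition of an essential set
#'
#' Counts essential genes per biotype and expresses each count as a
#' percentage of the expressed genes of that biotype, rounded to one
#' decimal.
#'
#' @param essential_ids Character vector of essential gene ids.
#' @param annotation Gene annotation data frame.
#' @param expressed_ids Character vector of all expressed gene ids (the
#'   denominator population).
#' @return Data frame with `biotype`, `n_essential`, `n_expressed`,
#'   `percent` (1-decimal percentage of expressed genes of that biotype).
#' @export
biotype_partition <- function(essential_ids, annotation, expressed_ids) {
  bt <- stats::setNames(annotation$biotype, annotation$gene_id)
  miss <- setdiff(c(essential_ids, expressed_ids), names(bt))
  if (length(miss))
    stop("unannotated gene(s): ", paste(utils::head(miss, 5), collapse = ", "),
         call. = FALSE)
  types <- c("lncRNA", "mRNA", "other")
  n_ess <- vapply(types, function(b) sum(bt[essential_ids] == b), integer(1))
  n_exp <- vapply(types, function(b) sum(bt[expressed_ids] == b), integer(1))
  pct <- ifelse(n_exp > 0, round(100 * n_ess / n_exp, 1), 0)
  data.frame(biotype = types, n_essential = n_ess, n_expressed = n_exp,
             percent = pct, row.names = NULL, stringsAsFactors = FALSE)
}

#' Percentage of a gene count over a population, 1-decimal
#'
#' Bookkeeping helper for printed summary fractions.
#'
#' @param n_hits Numerator count.
#' @param n_total Denominator count.
#' @return `round(100 * n_hits / n_total, 1)`.
#' @export
percent_of <- function(n_hits, n_total) {
  stopifnot(n_total > 0)
  round(100 * n_hits / n_total, 1)
}

#' Chromosome distribution of a gene set
#'
#' @param gene_ids Gene ids to summarize.
#' @param annotation Gene annotation with `chromosome` labels.
#' @param chrom_sizes Named numeric vector chromosome -> length (bp).
#' @param subset Chromosome labels forming the subset of interest.
#' @return List with `percent_genes` (share of the genes on the subset) and
#'   `percent_genome` (share of total genome length on the subset), both
#'   1-decimal percentages.
#' @export
chromosome_distribution <- function(gene_ids, annotation, chrom_sizes,
                                    subset) {
  chr <- stats::setNames(annotation$chromosome, annotation$gene_id)
  miss <- setdiff(gene_ids, names(chr))
  if (length(miss))
    stop("unannotated gene(s): ", paste(utils::head(miss, 5), collapse = ", "),
         call. = FALSE)
  used <- unique(chr[gene_ids])
  nosize <- setdiff(c(used, subset), names(chrom_sizes))
  if (length(nosize))
    stop("missing chromosome size(s): ", paste(nosize, collapse = ", "),
         call. = FALSE)
  list(
    percent_genes = percent_of(sum(chr[gene_ids] %in% subset),
                               length(gene_ids)),
    percent_genome = percent_of(sum(chrom_sizes[subset]), sum(chrom_sizes))
  )
}

#' Candidate lncRNAs: essential and differentially expressed
#'
#' Intersects an essential lncRNA set with a differential-expression result
#' restricted to significant lncRNAs, producing one candidate record per
#' shared gene, sorted by ascending adjusted p.
#'
#' @param essential_lnc Character vector of essential lncRNA ids.
#' @param de_table Data frame with at least `gene_id`, `adj_p` and a
#'   `direction` column naming the condition each gene is enriched in.
#' @param annotation Optional annotation supplying `symbol` and
#'   `chromosome` for the report.
#' @param scaled_degree Optional named scaled-degree vector to carry along.
#' @return Data frame with `gene_id`, `symbol`, `chromosome`,
#'   `scaled_degree`, `enriched_in`, `adj_p`, sorted by `adj_p`.
#' @export
overlap_candidates <- function(essential_lnc, de_table, annotation = NULL,
                               scaled_degree = NULL) {
  stopifnot(all(c("gene_id", "adj_p", "direction") %in% colnames(de_table)))
  hit <- de_table[de_table$gene_id %in% essential_lnc, , drop = FALSE]
  sym <- chrom <- rep(NA_character_, nrow(hit))
  if (!is.null(annotation)) {
    i <- match(hit$gene_id, annotation$gene_id)
    sym <- annotation$symbol[i]
    chrom <- annotation$chromosome[i]
  }
  sd <- if (is.null(scaled_degree)) rep(NA_real_, nrow(hit)) else
    unname(scaled_degree[hit$gene_id])
  out <- data.frame(gene_id = hit$gene_id, symbol = sym, chromosome = chrom,
                    scaled_degree = sd, enriched_in = hit$direction,
                    adj_p = hit$adj_p, stringsAsFactors = FALSE)
  out <- out[order(out$adj_p, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fisher-exact over-representation of gene sets
#'
#' One row per term: the one-sided (over-representation) Fisher exact test
#' of the 2x2 table formed by study/population membership against term
#' membership, with optional Benjamini-Hochberg adjustment.
#'
#' @param study Study gene set (must be a subset of `population`).
#' @param population Background gene set.
#' @param term2genes Named list term -> gene ids (intersected with the
#'   population).
#' @param adjust `"BH"` (default) or `"none"`.
#' @param alternative `"greater"` (over-representation, default) or
#'   `"two.sided"`.
#' @return Data frame with `term`, `study_hits`, `study_size`, `pop_hits`,
#'   `pop_size`, `p`, `adj_p`, sorted by `p`.
#' @export
fisher_enrichment <- function(study, population, term2genes,
                              adjust = c("BH", "none"),
                              alternative = c("greater", "two.sided")) {
  adjust <- match.arg(adjust)
  alternative <- match.arg(alternative)
  if (!length(population)) stop("empty population", call. = FALSE)
  if (!all(study %in% population))
    stop("study set must be a subset of the population", call. = FALSE)
  study <- unique(study); population <- unique(population)
  N <- length(population); n <- length(study)
  rows <- lapply(names(term2genes), function(tm) {
    tg <- intersect(term2genes[[tm]], population)
    K <- length(tg)
    k <- length(intersect(tg, study))
    tab <- matrix(c(k, n - k, K - k, N - n - (K - k)), nrow = 2)
    p <- stats::fisher.test(tab, alternative = alternative)$p.value
    data.frame(term = tm, study_hits = k, study_size = n, pop_hits = K,
               pop_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- if (adjust == "BH") stats::p.adjust(out$p, "BH") else out$p
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
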