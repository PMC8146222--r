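## Pipeline wrappers composing the stages into the two screens, with TSV
## report writers. Every emitted file starts with `#` header lines carrying
## the package version, a config hash and the seed, so identical inputs and
## config produce identical files.

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(names(config),
                   vapply(config, function(v) paste(format(v), collapse = ","),
                          character(1)),
                   sep = "="), f)
  unname(tools::md5sum(f))
}

.report_header <- function(config, seed) {
  c(paste0("coexscreen ", as.character(utils::packageVersion("coexscreen"))),
    paste0("config_hash: ", .config_hash(config)),
    paste0("seed: ", if (is.null(seed)) "NA" else seed))
}

.write_report <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df))
    writeLines(do.call(paste, c(lapply(df, function(col)
      if (is.numeric(col)) sprintf("%.10g", col) else as.character(col)),
      sep = "\t")), con)
  invisible(path)
}

#' Essential-gene screen over a network fit
#'
#' Selects the top-`top_fraction` intramodular-degree genes per module and,
#' when an annotation is supplied, attaches biotypes and the biotype
#' partition relative to the expressed gene set.
#'
#' @param fit A [coexp_fit()].
#' @param annotation Optional gene annotation.
#' @param top_fraction Fraction selected per module (default 0.25).
#' @return List with `essential` (data frame; plus `biotype` column when
#'   annotated) and `partition` (see [biotype_partition()], or `NULL`).
#' @export
essential_screen <- function(fit, annotation = NULL, top_fraction = 0.25) {
  kim <- stats::setNames(fit$connectivity$kim, fit$connectivity$gene_id)
  ess <- essential_genes(fit$assignment, kim, top_fraction = top_fraction)
  part <- NULL
  if (!is.null(annotation)) {
    bt <- stats::setNames(annotation$biotype, annotation$gene_id)
    ess$biotype <- unname(bt[ess$gene_id])
    part <- biotype_partition(ess$gene_id, annotation,
                              names(fit$assignment))
  }
  list(essential = ess, partition = part)
}

#' Run the essential-gene screen end to end and write its artifacts
#'
#' Filter, biotype-restrict, fit the network, detect and merge modules,
#' rank by intramodular degree and write three TSVs to `out_dir`:
#' `essential_genes.tsv`, `module_assignment.tsv` and (when the power scan
#' ran) `power_fits.tsv`.
#'
#' @param x FPKM matrix.
#' @param annotation Gene annotation.
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @param seed Seed recorded in the file headers (the screen itself is
#'   deterministic given its inputs).
#' @param top_fraction Essentiality fraction (default 0.25).
#' @param ... Passed to [coexp_fit()].
#' @return List with `fit`, `essential`, `partition`, `files`.
#' @export
run_essential_screen <- function(x, annotation = NULL, out_dir = NULL,
                                 seed = NULL, top_fraction = 0.25, ...) {
  fit <- coexp_fit(x, annotation = annotation, ...)
  scr <- essential_screen(fit, annotation, top_fraction = top_fraction)
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    config <- c(fit$params, list(beta = fit$beta,
                                 top_fraction = top_fraction))
    hdr <- .report_header(config, seed)
    files <- c(
      essential = .write_report(scr$essential,
                                file.path(out_dir, "essential_genes.tsv"),
                                hdr),
      modules = .write_report(
        data.frame(gene_id = names(fit$assignment),
                   module = unname(fit$assignment)),
        file.path(out_dir, "module_assignment.tsv"), hdr))
    if (!is.null(fit$power_fits))
      files["power_fits"] <- .write_report(
        fit$power_fits, file.path(out_dir, "power_fits.tsv"), hdr)
  }
  list(fit = fit, essential = scr$essential, partition = scr$partition,
       files = files)
}

#' Candidate screen: essential lncRNAs that are differentially expressed
#'
#' Intersects the essential lncRNAs with the significant lncRNAs of a DE
#' table and emits candidate records sorted by ascending adjusted p.
#'
#' @param essential Essential-gene data frame (from
#'   [run_essential_screen()] or [essential_screen()], with a `biotype`
#'   column).
#' @param de_table DE results (e.g. [load_de_results()] output); only rows
#'   with `significant = TRUE` (or all rows if no such column) are used.
#' @param annotation Gene annotation (supplies symbol/chromosome and
#'   restricts the DE table to lncRNAs).
#' @param out_dir Optional output directory for `candidates.tsv`.
#' @param seed Seed recorded in the file header.
#' @return Candidate data frame (see [overlap_candidates()]).
#' @export
run_candidate_screen <- function(essential, de_table, annotation,
                                 out_dir = NULL, seed = NULL) {
  if (nrow(de_table) && !any(de_table$gene_id %in% annotation$gene_id))
    stop("DE table and annotation share no gene ids", call. = FALSE)
  bt <- stats::setNames(annotation$biotype, annotation$gene_id)
  de <- de_table
  if ("significant" %in% colnames(de)) de <- de[de$significant, , drop = FALSE]
  de <- de[!is.na(bt[de$gene_id]) & bt[de$gene_id] == "lncRNA", ,
           drop = FALSE]
  ess_lnc <- essential$gene_id[essential$biotype == "lncRNA"]
  sd_vec <- stats::setNames(essential$scaled_degree, essential$gene_id)
  cand <- overlap_candidates(ess_lnc, de, annotation, sd_vec)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- .report_header(list(stage = "candidate_screen"), seed)
    .write_report(cand, file.path(out_dir, "candidates.tsv"), hdr)
  }
  cand
}

#' Regulator screen over a time course
#'
#' Correlates candidate regulators with the target across time points,
#' attaches exact correlation-test p-values, classifies by the inclusive
#' strong-correlation cuts and sorts by descending `|r|`.
#'
#' @param tc Time-course matrix (gene rows, >= 3 time-point columns).
#' @param target Target gene id.
#' @param candidates Candidate regulator ids.
#' @param pos_cut,neg_cut Classification cuts (defaults 0.95 / -0.95).
#' @param out_dir Optional output directory for `regulators.tsv`.
#' @param seed Seed recorded in the file header.
#' @return Data frame with `gene_id`, `r`, `p`, `class`.
#' @export
run_regulator_screen <- function(tc, target, candidates,
                                 pos_cut = 0.95, neg_cut = -0.95,
                                 out_dir = NULL, seed = NULL) {
  rec <- correlate_with_target(tc, target, candidates)
  rec <- classify_regulators(rec, pos_cut = pos_cut, neg_cut = neg_cut)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- .report_header(list(stage = "regulator_screen",
                               pos_cut = pos_cut, neg_cut = neg_cut), seed)
    .write_report(rec, file.path(out_dir, "regulators.tsv"), hdr)
  }
  rec
}
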