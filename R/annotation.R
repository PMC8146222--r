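## Gene annotation: id, symbol, biotype in {lncRNA, mRNA, other}, chromosome.

# GENCODE gene_type -> package biotype. Anything unlisted maps to "other".
.biotype_map <- c(
  protein_coding = "mRNA",
  lncRNA         = "lncRNA",
  lincRNA        = "lncRNA",
  antisense      = "lncRNA"
)

map_biotype <- function(gene_type) {
  out <- unname(.biotype_map[gene_type])
  out[is.na(out)] <- "other"
  out
}

#' Read gene annotation
#'
#' Reads per-gene annotation from either a GENCODE-style GTF (gene features
#' only; `gene_id`, `gene_name`, `gene_type` attributes) or a flat TSV with
#' columns `gene_id`, `symbol`, `biotype`, `chromosome`. GTF `gene_type`
#' values are mapped to the closed biotype set: `protein_coding` to `mRNA`,
#' lncRNA classes to `lncRNA`, everything else to `other`.
#'
#' @param path Path to the annotation file.
#' @param dialect `"tsv"` or `"gtf"`. The gtf dialect requires the
#'   rtracklayer package.
#' @return `data.frame` with columns `gene_id`, `symbol`, `biotype`,
#'   `chromosome`, one row per gene.
#' @export
read_gene_annotation <- function(path, dialect = c("tsv", "gtf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "tsv") {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, comment.char = "#")
    need <- c("gene_id", "symbol", "biotype", "chromosome")
    miss <- setdiff(need, colnames(tab))
    if (length(miss))
      stop("annotation TSV missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    ann <- tab[, need]
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("the gtf dialect requires the rtracklayer package", call. = FALSE)
    gr <- tryCatch(rtracklayer::import(path, format = "gtf",
                                       feature.type = "gene"),
                   error = function(e)
                     stop("failed to parse GTF '", path, "': ",
                          conditionMessage(e), call. = FALSE))
    md <- as.data.frame(gr)
    for (f in c("gene_id", "gene_type"))
      if (is.null(md[[f]]))
        stop("GTF gene features lack the '", f, "' attribute", call. = FALSE)
    ann <- data.frame(
      gene_id    = md$gene_id,
      symbol     = if (is.null(md$gene_name)) md$gene_id else md$gene_name,
      biotype    = map_biotype(md$gene_type),
      chromosome = as.character(md$seqnames),
      stringsAsFactors = FALSE
    )
  }
  validate_annotation(ann)
  ann
}

#' Validate a gene annotation table
#'
#' @param ann Annotation data frame.
#' @return `ann`, invisibly, if valid.
#' @export
validate_annotation <- function(ann) {
  stopifnot(is.data.frame(ann))
  need <- c("gene_id", "symbol", "biotype", "chromosome")
  miss <- setdiff(need, colnames(ann))
  if (length(miss))
    stop("annotation missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dup <- ann$gene_id[duplicated(ann$gene_id)]
  if (length(dup))
    stop("duplicated gene id(s) in annotation: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(ann$biotype), c("lncRNA", "mRNA", "other"))
  if (length(bad))
    stop("biotype(s) outside {lncRNA, mRNA, other}: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(ann)
}
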