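test_that("expression tables round-trip through TSV bit-identically", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t0\t1.5", "g2\t2\t0.25", "g3\t7\t3"), f)
  m <- read_expression_table(f)
  expect_identical(dim(m), c(3L, 2L))
  expect_identical(rownames(m), c("g1", "g2", "g3"))
  expect_equal(m["g2", "s2"], 0.25)

  set.seed(42)
  big <- matrix(round(stats::rexp(500 * 20), 6), 500, 20,
                dimnames = list(sprintf("g%03d", 1:500),
                                sprintf("s%02d", 1:20)))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(big, f2, comment = "synthetic")
  expect_identical(read_expression_table(f2), big)
})

test_that("malformed expression tables are rejected with the offending id", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g1\t3\t4"), f)
  expect_error(read_expression_table(f), "g1")
  writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g2\t-3\t4"), f)
  expect_error(read_expression_table(f), "g2")
})

test_that("filter_expressed keeps a gene at FPKM 0.1 in exactly 25% of samples", {
  vals <- rep(0, 20); vals[1:5] <- 0.1          # exactly 25% at the boundary
  m <- rbind(boundary = vals, below = c(0.1, rep(0, 19)),
             zero = rep(0, 20))
  colnames(m) <- paste0("s", 1:20)
  res <- filter_expressed(m)
  expect_true(res$kept[["boundary"]])
  expect_false(res$kept[["below"]])
  expect_false(res$kept[["zero"]])
})

test_that("filter_expressed matches a hand count on a 10-gene pattern", {
  # 4 samples, min_fraction 0.25: kept iff >= 1 sample at >= 0.1
  m <- toy_matrix(c(1, 0, 0, 0,      # kept
                    0, 0, 0, 0,      # removed
                    0.1, 0, 0, 0,    # kept (boundary)
                    0.09, 0.09, 0.09, 0.09,  # removed
                    5, 5, 5, 5,      # kept
                    0, 0, 0, 0.1,    # kept
                    0.05, 0, 0, 0,   # removed
                    0.2, 0.3, 0, 0,  # kept
                    0, 0.01, 0.02, 0.03,  # removed
                    10, 0, 0, 0),    # kept
                  paste0("g", 1:10), paste0("s", 1:4))
  res <- filter_expressed(m, 0.1, 0.25)
  expect_identical(sum(res$kept), 6L)
  expect_identical(rownames(res$matrix),
                   paste0("g", c(1, 3, 5, 6, 8, 10)))
})

test_that("filtering is monotone in both thresholds and commutes with biotype restriction", {
  set.seed(7)
  m <- matrix(stats::rexp(60 * 12, rate = 2), 60, 12,
              dimnames = list(paste0("g", 1:60), paste0("s", 1:12)))
  m[1:6, ] <- 5    # a few always-expressed genes so no subset is empty
  ann <- toy_annotation(paste0("g", 1:60),
                        rep(c("lncRNA", "mRNA", "other"), 20))
  for (mv in c(0.05, 0.2, 0.6)) for (mf in c(0.25, 0.5, 0.9)) {
    kept <- filter_expressed(m, mv, mf)$kept
    expect_true(all(filter_expressed(m, mv * 2, mf)$kept <= kept))
    expect_true(all(filter_expressed(m, mv, min(1, mf * 2))$kept <= kept))
    a <- restrict_biotypes(filter_expressed(m, mv, mf)$matrix, ann)
    b <- filter_expressed(restrict_biotypes(m, ann), mv, mf)$matrix
    expect_identical(rownames(a), rownames(b))
  }
})

test_that("restrict_biotypes keeps the requested classes", {
  m <- toy_matrix(rep(1:2, 4), paste0("g", 1:4), c("s1", "s2"))
  ann <- toy_annotation(paste0("g", 1:4),
                        c("mRNA", "mRNA", "lncRNA", "other"))
  expect_identical(nrow(restrict_biotypes(m, ann)), 3L)
  expect_identical(rownames(restrict_biotypes(m, ann, keep = "lncRNA")), "g3")
  expect_error(restrict_biotypes(m, ann[-1, ]), "g1")
})

test_that("biotype counts of a simulated gene set match the generator truth", {
  sim <- simulate_modular_expression(
    sim_config(module_sizes = c(200, 150), n_noise_genes = 150,
               lncRNA_fraction = 0.19, seed = 11))
  kept <- restrict_biotypes(sim$matrix, sim$annotation, keep = "lncRNA")
  expect_identical(nrow(kept), sum(sim$truth$biotype == "lncRNA"))
})

test_that("log_transform is exact, monotone and invertible", {
  m <- toy_matrix(c(0, 1, 3, 7), c("g1", "g2"), c("s1", "s2"))
  lt <- log_transform(m, base = 2)
  expect_equal(unname(lt["g1", ]), c(0, 1))
  expect_equal(unname(lt["g2", ]), c(2, 3))
  expect_error(log_transform(m, base = 1))
  expect_error(log_transform(m, base = -2))
  set.seed(3)
  x <- matrix(stats::rexp(50), 10, 5,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
  for (b in c(2, exp(1), 10)) {
    y <- log_transform(x, base = b)
    expect_equal(b^y - 1, x, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("max_normalize_per_gene scales rows to a unit maximum", {
  m <- toy_matrix(c(2, 4, 8, 5, 5, 5, 0, 0, 0),
                  c("a", "b", "c"), c("s1", "s2", "s3"))
  nm <- max_normalize_per_gene(m)
  expect_equal(unname(nm["a", ]), c(0.25, 0.5, 1))
  expect_equal(unname(nm["b", ]), c(1, 1, 1))
  expect_equal(unname(nm["c", ]), c(0, 0, 0))
  expect_identical(attr(nm, "flagged"), "c")
})

test_that("GTF gene_type values map onto the closed biotype set", {
  gtf <- c(
    'chr1\tX\tgene\t1\t100\t.\t+\t.\tgene_id "g1"; gene_name "A"; gene_type "protein_coding";',
    'chr2\tX\tgene\t1\t100\t.\t-\t.\tgene_id "g2"; gene_name "B"; gene_type "lncRNA";',
    'chr3\tX\tgene\t1\t100\t.\t+\t.\tgene_id "g3"; gene_name "C"; gene_type "snoRNA";',
    'chr3\tX\ttranscript\t1\t50\t.\t+\t.\tgene_id "g3"; transcript_id "t1"; gene_type "snoRNA";')
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(gtf, f)
  ann <- read_gene_annotation(f, dialect = "gtf")
  expect_identical(nrow(ann), 3L)   # transcript feature ignored
  expect_identical(ann$biotype, c("mRNA", "lncRNA", "other"))
  expect_identical(ann$chromosome, c("chr1", "chr2", "chr3"))
  expect_identical(ann$symbol, c("A", "B", "C"))
})

test_that("annotation TSV dialect validates its columns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tsymbol\tbiotype\tchromosome",
               "g1\tA\tmRNA\tchr1", "g2\tB\tlncRNA\tchr2"), f)
  ann <- read_gene_annotation(f, dialect = "tsv")
  expect_identical(ann$biotype, c("mRNA", "lncRNA"))
  writeLines(c("gene_id\tsymbol\tbiotype\tchromosome",
               "g1\tA\tweird\tchr1"), f)
  expect_error(read_gene_annotation(f, dialect = "tsv"), "weird")
})
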