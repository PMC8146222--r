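# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive (explicit loops, textbook definitions) so they cannot
# share a bug with the vectorized implementations they check.

# gene x sample matrix with given rownames/colnames
toy_matrix <- function(values, genes, samples) {
  m <- matrix(values, nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, samples))
  m
}

toy_annotation <- function(gene_id, biotype,
                           chromosome = rep("chr1", length(gene_id))) {
  data.frame(gene_id = gene_id, symbol = gene_id, biotype = biotype,
             chromosome = chromosome, stringsAsFactors = FALSE)
}

# Pearson correlation by the textbook sum formula
cor_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sx <- sqrt(sum((x - mx)^2) / (n - 1))
  sy <- sqrt(sum((y - my)^2) / (n - 1))
  sum((x - mx) * (y - my)) / ((n - 1) * sx * sy)
}

# TOM by the triple loop definition
tom_oracle <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  out <- matrix(1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    L <- 0
    for (u in seq_len(n)) if (u != i && u != j) L <- L + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    out[i, j] <- (L + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  out
}

# random symmetric adjacency in [0,1] with unit diagonal
random_adjacency <- function(n) {
  a <- matrix(stats::runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  a
}

# Benjamini-Hochberg by the direct definition:
# adj_i = min over { j : p_j >= p_i } of min(1, n * p_j / rank_j)
bh_oracle <- function(p) {
  n <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(n), function(i) {
    cand <- which(p >= p[i])
    min(1, min(n * p[cand] / r[cand]))
  }, numeric(1))
}

# average linkage (UPGMA) heights for a small dissimilarity, naive version
upgma_heights <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestv <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      v <- mean(d[clusters[[i]], clusters[[j]]])
      if (v < bestv) { bestv <- v; best <- c(i, j) }
    }
    heights <- c(heights, bestv)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# closed-form two-sided correlation-test p for n = 6 (df = 4), obtained by
# integrating the df-4 t density
pval6_closed <- function(r) 1 - 1.5 * abs(r) + 0.5 * abs(r)^3
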