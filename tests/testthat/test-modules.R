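test_that("average-linkage clustering separates planted blocks and matches UPGMA by hand", {
  d <- matrix(0.9, 10, 10)
  d[1:5, 1:5] <- 0.1; d[6:10, 6:10] <- 0.1
  diag(d) <- 0
  dimnames(d) <- list(paste0("g", 1:10), paste0("g", 1:10))
  hc <- hierarchical_cluster(d)
  top <- stats::cutree(hc, k = 2)
  expect_identical(length(unique(top[1:5])), 1L)
  expect_identical(length(unique(top[6:10])), 1L)
  expect_false(top[1] == top[6])

  # identical rows merge first at height zero
  m <- matrix(c(0, 0, 0.5, 0, 0, 0.5, 0.5, 0.5, 0), 3, 3)
  dimnames(m) <- list(letters[1:3], letters[1:3])
  hc2 <- hierarchical_cluster(m)
  expect_equal(hc2$height[1], 0)

  # 4-leaf case against the naive UPGMA oracle
  d4 <- matrix(0, 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  d4["a", "b"] <- d4["b", "a"] <- 0.2
  d4["a", "c"] <- d4["c", "a"] <- 0.5
  d4["b", "c"] <- d4["c", "b"] <- 0.6
  d4["a", "d"] <- d4["d", "a"] <- 0.9
  d4["b", "d"] <- d4["d", "b"] <- 0.8
  d4["c", "d"] <- d4["d", "c"] <- 0.7
  hc4 <- hierarchical_cluster(d4)
  expect_equal(hc4$height, c(0.2, 0.55, 0.8), tolerance = 1e-12)
  expect_equal(hc4$height, upgma_heights(d4), tolerance = 1e-12)

  expect_error(hierarchical_cluster(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

# dissTOM dendrogram for simulated data at a fixed power
sim_dendro <- function(sim, beta = 6) {
  lm2 <- log_transform(sim$matrix)
  hierarchical_cluster(diss_tom(topological_overlap(
    signed_adjacency(correlation_matrix(lm2), beta))))
}

test_that("dynamic tree cut recovers planted blocks and sends noise to grey", {
  sim <- simulate_modular_expression(
    sim_config(module_sizes = c(40, 40, 40), n_noise_genes = 0,
               noise_sd = 0.2, seed = 31))
  asg <- dynamic_tree_cut(sim_dendro(sim), min_module_size = 30)
  expect_identical(sort(unique(asg)), c("M1", "M2", "M3"))
  expect_identical(sum(asg == "grey"), 0L)
  for (m in unique(sim$truth$module))
    expect_identical(length(unique(asg[sim$truth$gene_id[
      sim$truth$module == m]])), 1L)

  sim2 <- simulate_modular_expression(
    sim_config(module_sizes = 40, n_noise_genes = 10, noise_sd = 0.2,
               seed = 32))
  asg2 <- dynamic_tree_cut(sim_dendro(sim2), min_module_size = 30)
  noise <- sim2$truth$gene_id[is.na(sim2$truth$module)]
  expect_identical(unname(asg2[noise]), rep("grey", 10))
  expect_identical(sum(asg2 != "grey"), 40L)

  expect_warning(
    asg3 <- dynamic_tree_cut(sim_dendro(sim2), min_module_size = 60),
    "grey")
  expect_true(all(asg3 == "grey"))
})

test_that("module labels partition the gene set and sizes sum to n", {
  sim <- simulate_modular_expression(
    sim_config(module_sizes = c(35, 30), n_noise_genes = 15, seed = 33))
  asg <- dynamic_tree_cut(sim_dendro(sim), min_module_size = 20)
  expect_identical(length(asg), nrow(sim$matrix))
  expect_identical(sum(table(asg)), nrow(sim$matrix))
  expect_setequal(names(asg), rownames(sim$matrix))
})

test_that("module eigengene is the first PC of the standardized module", {
  # identical profiles: eigengene proportional to the shared profile
  prof <- c(1, 3, 2, 5, 4, 6)
  m <- rbind(g1 = prof, g2 = 2 * prof + 1, g3 = 0.5 * prof - 2)
  colnames(m) <- paste0("s", 1:6)
  eg <- module_eigengene(m, rownames(m))
  expect_equal(eg$variance_explained, 1, tolerance = 1e-12)
  expect_equal(abs(stats::cor(eg$scores, prof)), 1, tolerance = 1e-12)
  expect_gt(stats::cor(eg$scores, prof), 0)   # oriented with mean profile
  expect_equal(sum(eg$scores^2), 1, tolerance = 1e-12)

  # anti-correlated pair: variance explained 1, documented sign tie-break
  m2 <- rbind(g1 = prof, g2 = -prof)
  colnames(m2) <- paste0("s", 1:6)
  eg2 <- module_eigengene(m2, rownames(m2))
  expect_equal(eg2$variance_explained, 1, tolerance = 1e-12)
  expect_gte(eg2$scores[1], 0)

  # random module against a brute-force eigendecomposition
  set.seed(14)
  m3 <- matrix(stats::rnorm(20 * 8), 20, 8,
               dimnames = list(paste0("g", 1:20), paste0("s", 1:8)))
  eg3 <- module_eigengene(m3, rownames(m3))
  z <- t(scale(t(m3)))
  ev <- eigen(t(z) %*% z, symmetric = TRUE)
  expect_equal(abs(sum(eg3$scores * ev$vectors[, 1])), 1, tolerance = 1e-8)
  expect_equal(eg3$variance_explained, ev$values[1] / sum(ev$values),
               tolerance = 1e-8)

  expect_error(module_eigengene(rbind(g1 = rep(2, 4)), "g1"), "constant")
})

test_that("eigengene merging joins split modules and leaves independent ones alone", {
  sim <- simulate_modular_expression(
    sim_config(module_sizes = 60, n_noise_genes = 0, noise_sd = 0.3,
               seed = 41))
  lm2 <- log_transform(sim$matrix)
  split <- stats::setNames(rep(c("Ma", "Mb"), each = 30), rownames(lm2))
  merged <- merge_modules(lm2, split, cor_threshold = 0.85)
  expect_identical(unname(unique(merged)), "M1")

  sim2 <- simulate_modular_expression(
    sim_config(module_sizes = c(40, 40), n_noise_genes = 0,
               noise_sd = 0.3, seed = 42))
  lm3 <- log_transform(sim2$matrix)
  truth2 <- stats::setNames(
    paste0("M", as.integer(factor(sim2$truth$module))),
    sim2$truth$gene_id)
  kept <- merge_modules(lm3, truth2, cor_threshold = 0.85)
  expect_identical(length(unique(kept)), 2L)
  expect_identical(unname(kept), unname(relabel_by_size(truth2)))

  unchanged <- merge_modules(lm3, truth2, cor_threshold = 1.01)
  expect_identical(length(unique(unchanged)), 2L)
})

test_that("no post-merge eigengene pair reaches the merge threshold", {
  for (s in c(51, 52)) {
    sim <- simulate_modular_expression(
      sim_config(module_sizes = c(40, 35, 30), n_noise_genes = 10,
                 seed = s))
    lm2 <- log_transform(sim$matrix)
    asg <- dynamic_tree_cut(sim_dendro(sim), min_module_size = 25)
    merged <- merge_modules(lm2, asg, cor_threshold = 0.85)
    mods <- setdiff(unique(merged), "grey")
    if (length(mods) > 1) {
      eg <- module_eigengenes(lm2, merged)
      cc <- stats::cor(eg)
      expect_lt(max(cc[upper.tri(cc)]), 0.85)
    }
    expect_identical(sum(table(merged)), length(asg))
  }
})
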