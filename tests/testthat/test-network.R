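test_that("correlation_matrix matches the direct formula and handles degenerate rows", {
  set.seed(5)
  m <- matrix(stats::rnorm(24), 4, 6,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  cc <- correlation_matrix(m)
  for (i in 1:4) for (j in 1:4)
    expect_equal(cc[i, j],
                 if (i == j) 1 else cor_oracle(m[i, ], m[j, ]),
                 tolerance = 1e-12)
  dup <- rbind(m, g5 = m["g1", ], g6 = -m["g2", ] + 3)
  cc2 <- correlation_matrix(dup)
  expect_equal(cc2["g1", "g5"], 1)
  expect_equal(cc2["g2", "g6"], -1)
  flat <- rbind(m, g7 = rep(2, 6))
  expect_error(correlation_matrix(flat), "g7")
  expect_warning(cc3 <- correlation_matrix(flat, strict = FALSE), "dropped")
  expect_identical(nrow(cc3), 4L)
})

test_that("signed adjacency maps correlation into [0,1] and is monotone in beta", {
  cc <- matrix(c(1, 1, -1, 0.5,
                 1, 1, -1, 0.5,
                 -1, -1, 1, 0,
                 0.5, 0.5, 0, 1), 4, 4)
  a <- signed_adjacency(cc, 19)
  expect_equal(a[1, 2], 1)
  expect_equal(a[1, 3], 0)
  expect_equal(signed_adjacency(matrix(c(1, 0, 0, 1), 2), 19)[1, 2],
               0.5^19, tolerance = 1e-15)
  set.seed(1)
  r <- stats::runif(20, -1, 1 - 1e-6)
  m <- diag(2)
  for (ri in r) {
    m[1, 2] <- m[2, 1] <- ri
    vals <- vapply(1:6, function(b) signed_adjacency(m, b)[1, 2], numeric(1))
    expect_true(all(diff(vals) < 0))
  }
  one <- diag(2); one[1, 2] <- one[2, 1] <- 1
  expect_true(all(vapply(1:6, function(b) signed_adjacency(one, b)[1, 2],
                         numeric(1)) == 1))
})

test_that("scale_free_fit scores a power law high and flat distributions low", {
  # degrees following p(k) ~ k^-2, by explicit counts
  ks <- 1:40
  counts <- round(4000 / ks^2)
  k <- rep(ks, counts)
  sf <- scale_free_fit(k)
  expect_gt(sf$fit_index, 0.95)
  expect_lt(sf$slope, 0)

  expect_error(scale_free_fit(rep(3, 100)), "degenerate")
  # dense near-uniform connectivity: all genes alike, no power-law decay
  set.seed(2)
  flatk <- 50 + stats::rnorm(200, sd = 1)
  expect_lt(scale_free_fit(flatk)$fit_index, 0.5)
})

test_that("pick_soft_threshold honors the cut, falls back, and is internally consistent", {
  sim <- simulate_modular_expression(
    sim_config(module_sizes = c(60, 40), n_noise_genes = 20, seed = 3))
  lm2 <- log_transform(filter_expressed(sim$matrix)$matrix)
  sel <- suppressWarnings(pick_soft_threshold(lm2, powers = 1:12))
  tab <- sel$fits
  if (!sel$warning_flag) {
    qual <- tab$power[!is.na(tab$fit_index) & tab$fit_index >= 0.8]
    expect_identical(sel$beta, min(qual))
  } else {
    expect_identical(sel$beta, tab$power[which.max(tab$fit_index)])
  }
  sel0 <- pick_soft_threshold(lm2, powers = 3:8, fit_cut = 0)
  qual0 <- sel0$fits$power[!is.na(sel0$fits$fit_index) &
                             sel0$fits$fit_index >= 0]
  expect_identical(sel0$beta, min(qual0))
  expect_false(sel0$warning_flag)
  expect_warning(selx <- pick_soft_threshold(lm2, powers = 3:8,
                                             fit_cut = 1.01),
                 "fall")
  expect_true(selx$warning_flag)
})

test_that("topological overlap reduces algebraically on 2-gene and complete graphs", {
  a <- matrix(c(1, 0.37, 0.37, 1), 2,
              dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(topological_overlap(a)["x", "y"], 0.37)
  full <- matrix(1, 5, 5, dimnames = list(paste0("g", 1:5), paste0("g", 1:5)))
  expect_true(all(topological_overlap(full) == 1))
})

test_that("topological overlap equals the triple-loop oracle on random networks", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(5:10, 1)
    a <- random_adjacency(n)
    tom <- topological_overlap(a)
    expect_lt(max(abs(tom - tom_oracle(a))), 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_lt(max(abs(tom - t(tom))), 1e-12)
  }
})

test_that("dissTOM is the exact complement of TOM", {
  set.seed(4)
  tom <- topological_overlap(random_adjacency(6))
  d <- diss_tom(tom)
  expect_true(all(diag(d) == 0))
  off <- upper.tri(d)
  expect_equal(d[off] + tom[off], rep(1, sum(off)))
})

test_that("connectivity matches brute-force sums, overall and within modules", {
  a3 <- matrix(0.5, 3, 3); diag(a3) <- 1
  dimnames(a3) <- list(paste0("g", 1:3), paste0("g", 1:3))
  expect_equal(unname(connectivity(a3)), c(1, 1, 1))

  set.seed(8)
  a <- random_adjacency(8)
  asg <- stats::setNames(rep(c("M1", "M2"), each = 4), rownames(a))
  conn <- connectivity(a, asg)
  for (i in 1:8) {
    k_bf <- 0; kim_bf <- 0
    for (j in 1:8) {
      if (j == i) next
      k_bf <- k_bf + a[i, j]
      if (asg[j] == asg[i]) kim_bf <- kim_bf + a[i, j]
    }
    expect_equal(conn$k[i], k_bf, tolerance = 1e-12)
    expect_equal(conn$kim[i], kim_bf, tolerance = 1e-12)
  }
  solo <- stats::setNames(c("M1", rep("M2", 7)), rownames(a))
  expect_equal(connectivity(a, solo)$kim[1], 0)
})

test_that("scaled intramodular degree peaks at 1 per module and flags hubs", {
  kim <- stats::setNames(c(4, 2, 2, 3, 3), paste0("g", 1:5))
  asg <- stats::setNames(c("M1", "M1", "M1", "M2", "M2"), paste0("g", 1:5))
  sd <- scaled_intramodular_degree(kim, asg)
  expect_equal(unname(sd), c(1, 0.5, 0.5, 1, 1))
  zero <- stats::setNames(c(0, 0), c("a", "b"))
  expect_warning(
    sd0 <- scaled_intramodular_degree(zero,
                                      stats::setNames(c("M1", "M1"),
                                                      c("a", "b"))),
    "zero")
  expect_equal(unname(sd0), c(0, 0))

  sim <- simulate_modular_expression(
    sim_config(module_sizes = 50, n_noise_genes = 0, noise_sd = 0.3,
               seed = 21))
  lm2 <- log_transform(sim$matrix)
  adj <- signed_adjacency(correlation_matrix(lm2), 6)
  asg1 <- stats::setNames(rep("M1", 50), rownames(adj))
  conn <- connectivity(adj, asg1)
  kimv <- stats::setNames(conn$kim, conn$gene_id)
  hub <- sim$truth$gene_id[sim$truth$is_hub]
  sdv <- scaled_intramodular_degree(kimv, asg1)
  # the planted hub carries the maximal loading; top scaled degree ~ 1
  expect_gt(sdv[hub], 0.95)
})

test_that("network results are invariant to the log base", {
  sim <- simulate_modular_expression(
    sim_config(module_sizes = c(30, 25), n_noise_genes = 5, seed = 13))
  l2 <- log_transform(sim$matrix, base = 2)
  le <- log_transform(sim$matrix, base = exp(1))
  c2 <- correlation_matrix(l2); ce <- correlation_matrix(le)
  expect_lt(max(abs(c2 - ce)), 1e-10)
  expect_lt(max(abs(topological_overlap(signed_adjacency(c2, 7)) -
                    topological_overlap(signed_adjacency(ce, 7)))), 1e-10)
})
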