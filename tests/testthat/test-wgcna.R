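test_that("pearson correlation matches the definitional two-pass formula", {
  x <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1))
  r <- pearson_correlation(x)
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_equal(diag(r), setNames(rep(1, 3), rownames(x)))

  set.seed(11)
  y <- matrix(rnorm(50 * 8), 50, dimnames = list(paste0("g", 1:50), NULL))
  expect_equal(pearson_correlation(y), bf_correlation(y), tolerance = 1e-12)

  y[3, ] <- 5
  expect_error(pearson_correlation(y), "g3")
})

test_that("soft adjacency is the unsigned power transform", {
  r <- matrix(c(1, 0.9, 0.9, 1), 2)
  expect_equal(soft_adjacency(r, 10)[1, 2], 0.34867844, tolerance = 1e-8)
  r_neg <- matrix(c(1, -1, -1, 1), 2)
  for (beta in c(1, 3, 10)) expect_equal(soft_adjacency(r_neg, beta)[1, 2], 1)
  r_rand <- random_adjacency(6) * 2 - 1
  diag(r_rand) <- 1
  expect_equal(soft_adjacency(r_rand, 1), abs(r_rand))
  expect_error(soft_adjacency(r, 0), "beta")
})

test_that("scale-free fit recovers an exact power law with signed R2 = 1", {
  # degree multiset {8 x deg1, 4 x deg2, 2 x deg4, 1 x deg8}: frequencies
  # halve as degree doubles, an exact log-log line of slope -1
  nodes <- c("C", "D1", "D2", paste0("B", 1:4), paste0("L", 1:8))
  edges <- rbind(
    cbind("C", c("D1", "D2", "B1", "B2", "B3", "B4", "L1", "L2")),
    cbind("D1", c("L3", "L4", "L5")), cbind("D2", c("L6", "L7", "L8")),
    c("B1", "B2"), c("B3", "B4"))
  a <- tom_from_edges(nodes, edges, weight = 1)
  fit <- scale_free_fit(a)
  expect_equal(fit$signed_r2, 1, tolerance = 1e-10)
  expect_equal(fit$slope, -1, tolerance = 1e-10)

  # all-equal connectivity is degenerate
  tri <- tom_from_edges(c("x", "y", "z"),
                        rbind(c("x", "y"), c("y", "z"), c("x", "z")), 1)
  expect_error(scale_free_fit(tri), "equal")

  # more high-degree than low-degree nodes: positive slope, negative index
  k6 <- matrix(1, 6, 6, dimnames = list(paste0("n", 1:6), paste0("n", 1:6)))
  k6["n1", "n2"] <- k6["n2", "n1"] <- 0
  fit_pos <- scale_free_fit(k6)
  expect_gt(fit_pos$slope, 0)
  expect_lt(fit_pos$signed_r2, 0)
})

test_that("soft-threshold selection is minimal, deterministic, and flags fallback", {
  sim <- simulate_experiment(small_sim_config(seed = 1))
  xf <- filter_by_variance(vst_transform(sim$counts), 50)

  pick <- pick_soft_threshold(xf, powers = 1:12, r2_cut = 0.5)
  expect_true(pick$reached_cut)
  below <- pick$report$power < pick$power
  expect_true(all(pick$report$signed_r2[below] < 0.5))
  expect_gte(pick$report$signed_r2[pick$report$power == pick$power], 0.5)

  # identical input, identical report (no hidden randomness)
  pick2 <- pick_soft_threshold(xf, powers = 1:12, r2_cut = 0.5)
  expect_identical(pick, pick2)

  # unreachable cut falls back to the best power and says so
  pick3 <- pick_soft_threshold(xf, powers = 1:12, r2_cut = 0.9999)
  expect_false(pick3$reached_cut)
  expect_equal(pick3$power,
               pick3$report$power[which.max(pick3$report$signed_r2)])

  # mean connectivity strictly decreases with the power
  expect_true(all(diff(pick$report$mean_k) < 0))
})

test_that("topological overlap matches the definition and the triple-loop oracle", {
  two <- matrix(c(1, 0.4, 0.4, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(tom_similarity(two)["a", "b"], 0.4)

  three <- matrix(0.5, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(three) <- 1
  t3 <- tom_similarity(three)
  expect_equal(unique(t3[upper.tri(t3)]), 0.5)

  set.seed(5)
  for (i in 1:25) {
    a <- random_adjacency(sample(4:12, 1))
    t_fast <- tom_similarity(a)
    expect_equal(t_fast, bf_tom(a), tolerance = 1e-12)
    expect_true(all(t_fast >= 0 & t_fast <= 1))
    expect_equal(t_fast, t(t_fast))
    expect_equal(unname(diag(t_fast)), rep(1, nrow(a)))
  }
})

test_that("module detection separates blocks, enforces the size rule, and is deterministic", {
  block_tom <- function(sizes, within = 0.8, between = 0.01) {
    n <- sum(sizes)
    m <- matrix(between, n, n)
    at <- cumsum(c(0, sizes))
    for (b in seq_along(sizes)) {
      idx <- (at[b] + 1):at[b + 1]
      m[idx, idx] <- within
    }
    diag(m) <- 1
    dimnames(m) <- list(paste0("g", 1:n), paste0("g", 1:n))
    m
  }
  two40 <- block_tom(c(40, 40))
  mods <- cluster_modules(two40, min_module_size = 35)
  expect_setequal(unique(mods), c("turquoise", "blue"))
  expect_equal(unname(table(mods)[c("turquoise", "blue")]),
               c(40L, 40L), ignore_attr = TRUE)
  expect_identical(mods, cluster_modules(two40, min_module_size = 35))

  two30 <- block_tom(c(30, 30))
  expect_true(all(cluster_modules(two30, min_module_size = 35) == "grey"))
  expect_error(cluster_modules(two30, min_module_size = 100), "exceeds")

  # size-ranked color names: largest block is turquoise
  uneven <- cluster_modules(block_tom(c(36, 50)), min_module_size = 35)
  expect_equal(sum(uneven == "turquoise"), 50L)
  expect_equal(sum(uneven == "blue"), 36L)
})

test_that("module eigengene is the oriented first principal component", {
  x <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8), g3 = c(1.5, 3, 4.5, 6))
  colnames(x) <- paste0("s", 1:4)
  eig <- module_eigengene(x, rownames(x))
  expect_equal(abs(cor(eig, x["g1", ])), 1, tolerance = 1e-10)
  expect_equal(sum(eig^2), 1)
  expect_gte(cor(eig, colMeans(x)), 0)

  expect_error(module_eigengene(x, c("g1", "nope")), "nope")

  # explains at least as much standardized variance as any single member
  set.seed(21)
  y <- matrix(rnorm(12 * 9), 12, dimnames = list(paste0("g", 1:12), NULL))
  colnames(y) <- paste0("s", 1:9)
  eig_y <- module_eigengene(y, rownames(y))
  z <- t(scale(t(y)))
  var_along <- function(v) sum((z %*% v / sqrt(sum(v^2)))^2)
  best_single <- max(apply(z, 1, var_along))
  expect_gte(var_along(eig_y) + 1e-10, best_single)
})

test_that("module-trait p-values reproduce the printed correlation/p pairs at n = 36", {
  expect_gte(cor_pvalue(0.46, 36), 0.004)
  expect_lte(cor_pvalue(0.46, 36), 0.005)
  expect_equal(round(cor_pvalue(0.34, 36), 2), 0.04)
  expect_equal(round(cor_pvalue(0.36, 36), 2), 0.03)
  expect_gt(cor_pvalue(1, 36), 0)          # perfect correlation: floored, not 0
  expect_lte(cor_pvalue(1, 36), 1e-100)
  expect_error(cor_pvalue(1.2, 36), "\\[-1, 1\\]")
})

test_that("module-trait relationships correlate eigengenes with design indicators", {
  sim <- simulate_experiment(small_sim_config(seed = 3))
  xf <- filter_by_variance(vst_transform(sim$counts), 50)
  design <- trait_design(sim$sheet)
  expect_true(all(rowSums(design) == 1))
  expect_true(all(grepl("^(ct|ss)_\\d+h$", colnames(design))))

  tom <- tom_similarity(soft_adjacency(pearson_correlation(xf), 10))
  mods <- cluster_modules(tom, 35, cut_fraction = 0.999)
  me <- module_eigengenes(xf, mods)
  mtr <- module_trait_relationships(me, design)
  expect_true(all(mtr$r >= -1 & mtr$r <= 1, na.rm = TRUE))
  expect_true(all(mtr$p > 0 & mtr$p <= 1, na.rm = TRUE))
  expect_equal(nrow(mtr), ncol(me) * ncol(design))

  # a constant indicator column is reported as missing
  design0 <- cbind(design, ct_99h = 0)
  mtr0 <- module_trait_relationships(me, design0)
  expect_true(all(is.na(mtr0$r[mtr0$trait == "ct_99h"])))
})
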