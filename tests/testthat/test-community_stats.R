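test_that("ANOSIM R hits its boundary and equivariance cases", {
  # two groups whose every between-pair distance exceeds every within-pair
  # distance: R = 1
  pts <- c(0, 1, 2, 10, 11, 12)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  g <- rep(c("a", "b"), each = 3)
  res <- anosim_test(d, g, n_permutations = 99, seed = 1)
  expect_equal(res$r_statistic, 1)
  expect_gte(res$p_value, 1 / 100) # +1 convention: p can never be 0

  # relabelling both inputs identically leaves R unchanged
  perm <- c(4, 1, 6, 2, 5, 3)
  res2 <- anosim_test(d[perm, perm], g[perm], n_permutations = 99, seed = 1)
  expect_equal(res2$r_statistic, res$r_statistic)

  # rank-based: any monotone transform of the distances gives identical R
  d_mono <- sqrt(d / (1 + d))
  expect_equal(anosim_test(d_mono, g, n_permutations = 9, seed = 1)$r_statistic,
               res$r_statistic)

  expect_error(anosim_test(d, rep(c("a", "b", "c"), c(4, 1, 1)),
                           n_permutations = 9), "fewer than 2")
})

test_that("ANOSIM agrees with an independent R-statistic oracle and vegan", {
  set.seed(13)
  pts <- matrix(rnorm(24), ncol = 2)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:12), paste0("s", 1:12))
  g <- rep(c("x", "y", "z"), each = 4)
  mine <- anosim_test(d, g, n_permutations = 99, seed = 2)
  expect_equal(mine$r_statistic, anosim_r_oracle(d, g), tolerance = 1e-12)
  skip_if_not_installed("vegan")
  ref <- vegan::anosim(as.dist(d), g, permutations = 99)
  expect_equal(mine$r_statistic, unname(ref$statistic), tolerance = 1e-12)
})

test_that("ANOSIM Monte-Carlo p matches exhaustive label enumeration on a 6-sample toy", {
  set.seed(17)
  pts <- c(0.0, 0.8, 2.4, 1.9, 3.4, 4.1) # partial overlap: p away from 1/(n+1)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  g <- rep(c("a", "b"), each = 3)
  r_obs <- anosim_r_oracle(d, g)
  # exact one-sided p over all 20 distinct 3|3 label partitions
  combos <- combn(6, 3)
  r_all <- apply(combos, 2, function(idx) {
    gg <- rep("b", 6); gg[idx] <- "a"
    anosim_r_oracle(d, gg)
  })
  p_exact <- mean(r_all >= r_obs - 1e-12)
  n_mc <- 1e5
  mc <- anosim_test(d, g, n_permutations = n_mc, seed = 3)
  se <- sqrt(p_exact * (1 - p_exact) / n_mc)
  expect_lt(abs(mc$p_value - p_exact), 3 * se + 2 / n_mc)
  # permutation null is centred near zero
  expect_lt(abs(mean(r_all)), 0.15)
})

test_that("Kruskal-Wallis matches hand rank arithmetic and the base-R oracle", {
  # maximal separation for n = 9, k = 3: H = 7.2
  v <- 1:9
  g <- rep(c("a", "b", "c"), each = 3)
  res <- kruskal_wallis(v, g)
  expect_equal(res$statistic, 7.2)
  expect_equal(res$df, 2)
  # cross-check statistic and p against stats::kruskal.test with ties
  set.seed(31)
  v2 <- round(rnorm(30), 1)
  g2 <- sample(rep(c("a", "b", "c"), each = 10))
  mine <- kruskal_wallis(v2, g2)
  ref <- kruskal.test(v2, factor(g2))
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  # degenerate: all values identical
  flat <- kruskal_wallis(rep(4, 9), g)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  # overwhelming shift is detected
  shift <- kruskal_wallis(c(rnorm(10), rnorm(10) + 10),
                          rep(c("a", "b"), each = 10))
  expect_lt(shift$p_value, 0.01)
})

test_that("Kruskal-Wallis holds its nominal type-I error under the null", {
  set.seed(101)
  n_sim <- 4000
  rejections <- 0
  g <- rep(c("a", "b", "c"), c(4, 13, 7))
  for (i in seq_len(n_sim)) {
    v <- rnorm(length(g))
    if (kruskal_wallis(v, g)$p_value < 0.05) rejections <- rejections + 1
  }
  rate <- rejections / n_sim
  se <- sqrt(0.05 * 0.95 / n_sim)
  # chi-square approximation is slightly conservative at these sizes
  expect_lt(abs(rate - 0.05), 3 * se + 0.01)
})

test_that("Mann-Whitney U matches enumeration, symmetry, and the base-R oracle", {
  # complete separation: min U = 0
  res <- mann_whitney(1:3, 4:6)
  expect_equal(res$statistic, 0)
  # identical multisets: U = n_a n_b / 2, p ~ 1
  res2 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res2$statistic, 4.5)
  expect_gt(res2$p_value, 0.9)
  # exact p equals wilcox.test's exact p without ties
  set.seed(7)
  x <- rnorm(8); y <- rnorm(9) + 0.5
  mine <- mann_whitney(x, y)
  ref <- wilcox.test(x, y, exact = TRUE, correct = FALSE)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  # normal approximation with ties matches wilcox.test's corrected p
  xt <- c(1, 2, 2, 3, 5, 5, 7); yt <- c(2, 3, 3, 4, 5, 8)
  expect_warning(tie_res <- mann_whitney(xt, yt, exact = TRUE), "ties")
  ref_t <- wilcox.test(xt, yt, exact = FALSE, correct = TRUE)
  expect_equal(tie_res$p_value, ref_t$p.value, tolerance = 1e-12)
})

test_that("exact and approximate Mann-Whitney p agree on 5x5 inputs", {
  set.seed(23)
  for (i in 1:20) {
    x <- rnorm(5); y <- rnorm(5)
    p_exact <- mann_whitney(x, y, exact = TRUE)$p_value
    p_norm <- mann_whitney(x, y, exact = FALSE)$p_value
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("Kruskal-Wallis with two groups approaches the Mann-Whitney z-squared", {
  set.seed(41)
  x <- rnorm(150); y <- rnorm(170) + 0.2
  h <- kruskal_wallis(c(x, y), rep(c("a", "b"), c(150, 170)))
  u <- mann_whitney(x, y)
  # both p-values derive from asymptotically identical statistics
  expect_lt(abs(h$p_value - u$p_value), 0.02)
})

test_that("pairwise ANOSIM covers every unordered group pair once", {
  set.seed(19)
  pts <- rnorm(15)
  d <- as.matrix(dist(pts))
  ids <- paste0("s", 1:15)
  dimnames(d) <- list(ids, ids)
  g <- setNames(rep(c("reference", "flooding", "recovery"), each = 5), ids)
  out <- pairwise_anosim(d, g, n_permutations = 99, seed = 5)
  expect_equal(nrow(out), 3) # k (k - 1) / 2 for k = 3
  expect_setequal(out$comparison,
                  c("flooding vs recovery", "flooding vs reference",
                    "recovery vs reference"))
  expect_true(all(out$p_value >= 1 / 100))
})
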