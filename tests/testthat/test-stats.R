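# Cluster permutation test, FDR, repeated-measures ANOVA, robust Spearman.

test_that("identical conditions produce no clusters", {
  set.seed(1)
  A <- matrix(rnorm(10 * 100), 10)
  cr <- cluster_permutation_test(A, A, n_perm = 200, seed = 3)
  expect_equal(nrow(cr$clusters), 0)
  expect_error(cluster_permutation_test(A[1, , drop = FALSE],
                                        A[1, , drop = FALSE], seed = 1),
               "at least 2")
  expect_error(cluster_permutation_test(A, A[, 1:50], seed = 1), "match")
  expect_error(cluster_permutation_test(A, A), "required")
})

test_that("an injected contiguous effect is found where it was injected", {
  set.seed(2)
  A <- matrix(rnorm(20 * 200), 20)
  B <- matrix(rnorm(20 * 200), 20)
  A[, 80:120] <- A[, 80:120] + 1.2 * sqrt(2)
  tm <- seq(0, 1.99, by = 0.01)
  cr <- cluster_permutation_test(A, B, time = tm, n_perm = 500, seed = 4)
  sig <- cr$clusters[cr$clusters$significant, ]
  expect_gte(nrow(sig), 1)
  top <- sig[which.max(abs(sig$mass)), ]
  expect_lt(top$start_s, 0.95)
  expect_gt(top$end_s, 1.05)
  expect_gt(top$mass, 0)
  expect_gte(min(cr$clusters$p), 1 / 501)   # plus-one floor
  # determinism under the seed
  cr2 <- cluster_permutation_test(A, B, time = tm, n_perm = 500, seed = 4)
  expect_identical(cr$clusters, cr2$clusters)
})

test_that("permutation p values are valid under the null", {
  # quick validity probe at three alpha levels (the full-scale family-wise
  # calibration lives in the acceptance suite)
  set.seed(5)
  pmins <- replicate(60, {
    A <- matrix(rnorm(12 * 60), 12)
    B <- matrix(rnorm(12 * 60), 12)
    cr <- cluster_permutation_test(A, B, n_perm = 150,
                                   seed = sample.int(1e6, 1))
    if (nrow(cr$clusters)) min(cr$clusters$p) else 1
  })
  for (a in c(0.05, 0.1, 0.2)) expect_lte(mean(pmins <= a), a + 0.1)
})

test_that("BH adjustment matches brute-force step-up enumeration", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(rep(0.04, 7)), rep(0.04, 7))
  p <- c(0.01, 0.02, 0.03, 0.04)
  # independent oracle: direct step-up computation
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  oracle <- numeric(m); oracle[o] <- pmin(adj, 1)
  expect_equal(fdr_adjust(p), oracle)
  set.seed(6)
  pr <- runif(50)
  o <- order(pr)
  adj <- pr[o] * 50 / seq_len(50)
  adj <- rev(cummin(rev(adj)))
  oracle <- numeric(50); oracle[o] <- pmin(adj, 1)
  expect_equal(fdr_adjust(pr), oracle)
  expect_true(all(fdr_adjust(pr) >= pr))
  expect_true(all(fdr_adjust(pr) <= 1))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("repeated-measures ANOVA matches the aov error-strata oracle", {
  set.seed(7)
  d <- expand.grid(subj = factor(1:8), A = factor(c("a1", "a2", "a3")),
                   B = factor(c("b1", "b2")))
  d$y <- rnorm(nrow(d)) + 0.6 * as.numeric(d$A) +
    0.3 * as.numeric(d$A) * as.numeric(d$B)
  res <- rm_anova(d, "y", "subj", c("A", "B"))
  fit <- summary(stats::aov(y ~ A * B + Error(subj / (A * B)), data = d))
  get <- function(stratum, row) {
    tab <- fit[[stratum]][[1]]
    unlist(tab[row, c("Df", "Sum Sq", "F value", "Pr(>F)")])
  }
  for (eff in c("A", "B", "A:B")) {
    stratum <- paste0("Error: subj:", eff)
    oracle <- get(stratum, eff)
    mine <- res[res$effect == eff, ]
    expect_equal(mine$df1, unname(oracle["Df"]))
    expect_equal(mine$SS, unname(oracle["Sum Sq"]), tolerance = 1e-8)
    expect_equal(mine$F, unname(oracle["F value"]), tolerance = 1e-8)
    expect_equal(mine$p, unname(oracle["Pr(>F)"]), tolerance = 1e-8)
  }
})

test_that("two-level factors give F equal to squared paired t and epsilon 1", {
  set.seed(8)
  d <- expand.grid(subj = factor(1:12), A = factor(c("x", "y")))
  d$y <- rnorm(24)
  res <- rm_anova(d, "y", "subj", "A")
  tt <- stats::t.test(d$y[d$A == "x"], d$y[d$A == "y"], paired = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  expect_equal(res$epsilon, 1)
})

test_that("rm ANOVA is invariant to subject relabeling and constant shifts", {
  set.seed(9)
  d <- expand.grid(subj = factor(1:6), A = factor(c("a", "b", "c")))
  d$y <- rnorm(18)
  r1 <- rm_anova(d, "y", "subj", "A")
  d2 <- d; d2$y <- d$y + 100
  r2 <- rm_anova(d2, "y", "subj", "A")
  expect_equal(r1$F, r2$F, tolerance = 1e-9)
  d3 <- d
  levels(d3$subj) <- rev(levels(d3$subj))
  r3 <- rm_anova(d3, "y", "subj", "A")
  expect_equal(sort(r1$F), sort(r3$F), tolerance = 1e-9)
  expect_error(rm_anova(d[-1, ], "y", "subj", "A"), "balanced")
  # Greenhouse-Geisser epsilon stays inside its admissible range
  expect_gte(r1$epsilon, 1 / 2)
  expect_lte(r1$epsilon, 1)
})

test_that("robust Spearman removes triple-flagged outliers only", {
  set.seed(10)
  x <- rnorm(30); y <- 0.6 * x + rnorm(30, 0, 0.4)
  x[31] <- 12; y[31] <- -12      # gross bivariate outlier
  r <- robust_spearman(x, y, sided = "one", direction = "positive")
  expect_true(31L %in% r$outliers)   # the gross point is always removed
  expect_equal(r$n_used, 31 - length(r$outliers))
  expect_equal(r$outliers,
               which(r$flags$boxplot & r$flags$mad & r$flags$s_outlier))
  # oracle: recompute each method flag directly
  box <- function(v) { q <- quantile(v, c(0.25, 0.75)); iqr <- diff(q)
    v < q[1] - 1.5 * iqr | v > q[2] + 1.5 * iqr }
  madr <- function(v) abs(v - median(v)) / mad(v) > 2.24
  sn1 <- function(v) { n <- length(v)
    s <- 1.1926 * median(vapply(seq_len(n), function(i)
      median(abs(v[i] - v[-i])), 0))
    abs(v - median(v)) / s > 2.24 }
  expect_equal(which(r$flags$boxplot), which(box(x) | box(y)))
  expect_equal(which(r$flags$mad), which(madr(x) | madr(y)))
  expect_equal(which(r$flags$s_outlier), which(sn1(x) | sn1(y)))
  # a point flagged by only some methods is retained
  x2 <- c(rnorm(25), 3.4); y2 <- c(rnorm(25), 0)
  r2 <- robust_spearman(x2, y2, sided = "two")
  common <- which(r2$flags$boxplot & r2$flags$mad & r2$flags$s_outlier)
  expect_equal(r2$outliers, common)
})

test_that("Spearman rho is monotone-invariant and near zero under the null", {
  x <- sort(rnorm(40)); y <- exp(0.8 * x)
  r <- robust_spearman(x, y, sided = "one", direction = "positive")
  expect_equal(r$rho, 1)
  # strictly monotone transforms of either variable leave rho unchanged
  r2 <- robust_spearman(exp(x), y, sided = "one", direction = "positive")
  expect_equal(r2$rho, r$rho)
  set.seed(11)
  xn <- rnorm(1000); yn <- rnorm(1000)
  rn <- robust_spearman(xn, yn, sided = "two")
  expect_lt(abs(rn$rho), 0.08)
  expect_error(robust_spearman(rnorm(4), rnorm(4), "two"), "fewer than 5")
})
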