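test_that("Lilliefors KS holds its level on normal data and rejects uniform", {
  set.seed(20)
  frac <- mean(replicate(200, ks_normality(rnorm(1000))$p > 0.05))
  expect_gte(frac, 0.92)   # nominal level 0.95; binomial noise over 200 reps
  set.seed(21)
  expect_lt(ks_normality(runif(500))$p, 0.01)
  expect_error(ks_normality(rnorm(4)), "n >= 5")
  expect_error(ks_normality(rep(1, 10)), "constant")
})

test_that("Friedman matches the hand-computed fixture and a brute-force oracle", {
  m <- cbind(a = c(1, 4, 7), b = c(2, 5, 8), c = c(3, 6, 9))
  ft <- friedman_test(m)
  expect_equal(ft$chi2, 6)            # 12/(3*3*4) * (9+36+81) - 3*3*4
  expect_equal(unname(ft$mean_ranks), c(1, 2, 3))
  # all cells equal -> zero statistic
  expect_equal(unname(friedman_test(matrix(rep(c(2, 2, 2), 4), 4, 3,
                                           byrow = TRUE))$chi2), 0)
  # column permutation permutes mean ranks identically
  set.seed(22)
  r <- matrix(rnorm(20), 5, 4)
  colnames(r) <- letters[1:4]
  f1 <- friedman_test(r)
  f2 <- friedman_test(r[, c(3, 1, 4, 2)])
  expect_equal(f2$mean_ranks[colnames(r)], f1$mean_ranks)
  expect_equal(f1$chi2, f2$chi2)
  # brute-force oracle on random no-tie matrices
  for (i in 1:5) {
    x <- matrix(rnorm(20), 5, 4)
    rk <- t(apply(x, 1, rank))
    chi_oracle <- 12 / (5 * 4 * 5) * sum(colSums(rk)^2) - 3 * 5 * 5
    expect_equal(unname(friedman_test(x)$chi2), chi_oracle)
  }
})

test_that("pairwise Wilcoxon flags degenerate pairs and detects a constant shift", {
  m <- cbind(a = rnorm(20), b = 0)
  m[, "b"] <- m[, "a"]
  w <- wilcoxon_pairwise(m)
  expect_true(w$degenerate[1])
  set.seed(23)
  x <- rnorm(20)
  m2 <- cbind(a = x + 1, b = x)
  w2 <- wilcoxon_pairwise(m2)
  expect_lt(w2$p[1], 0.01)
  # antisymmetric swap: same p, mirrored statistic
  w3 <- wilcoxon_pairwise(m2[, c(2, 1)])
  expect_equal(w2$p, w3$p)
  expect_equal(w2$W + w3$W, 20 * 21 / 2)
  wh <- wilcoxon_pairwise(cbind(a = x + 1, b = x, c = x - 1), "holm")
  expect_true(all(wh$p >= wilcoxon_pairwise(cbind(a = x + 1, b = x, c = x - 1))$p))
})

test_that("Kruskal-Wallis matches the hand-computed fixture and its invariances", {
  kw <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(kw$H, 32 / 7)           # 12/42 * (9/2 + 49/2 + 121/2) - 21
  # group-order permutation leaves (H, p) unchanged
  kw2 <- kruskal_wallis(list(c(5, 6), c(1, 2), c(3, 4)))
  expect_equal(kw2$H, kw$H)
  expect_equal(kw2$p, kw$p)
  expect_equal(kruskal_wallis(list(rep(2, 3), rep(2, 4)))$flag, "all_ties")
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
  # level under the null: one seeded sample split into two groups
  set.seed(24)
  frac <- mean(replicate(200, {
    z <- rnorm(40)
    kruskal_wallis(list(z[1:20], z[21:40]))$p > 0.05
  }))
  expect_gte(frac, 0.92)
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(25)
  m <- matrix(abs(rnorm(24)), 6, 4)
  expect_equal(friedman_test(exp(m))$chi2, friedman_test(m)$chi2)
  expect_equal(friedman_test(m^3)$mean_ranks, friedman_test(m)$mean_ranks)
  g <- list(abs(rnorm(5)), abs(rnorm(6)), abs(rnorm(7)))
  expect_equal(kruskal_wallis(lapply(g, log))$H, kruskal_wallis(g)$H)
})

test_that("sphericity diagnostics behave under compound symmetry and its violation", {
  set.seed(26)
  reps <- replicate(50, {
    d <- matrix(rnorm(160), 40, 4) + rnorm(40)   # compound-symmetric
    s <- sphericity_epsilon(d)
    c(p = s$p, eps = s$huynh_feldt_epsilon)
  })
  expect_gte(mean(reps["p", ] > 0.05), 0.85)
  expect_gt(mean(reps["eps", ]), 0.9)
  # one dominant condition variance violates sphericity, epsilon < 1
  set.seed(27)
  d <- matrix(rnorm(160), 40, 4)
  d[, 1] <- d[, 1] * 6
  s <- sphericity_epsilon(d)
  expect_lt(s$huynh_feldt_epsilon, 1)
  expect_lt(s$p, 0.05)
  expect_error(sphericity_epsilon(matrix(rnorm(80), 40, 2)), "3 conditions")
  expect_error(sphericity_epsilon(matrix(rnorm(12), 3, 4)), "more subjects")
})
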