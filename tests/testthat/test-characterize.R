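test_that("one-way ANOVA matches the aov oracle and its own identities", {
  set.seed(55)
  g <- factor(rep(c("a", "b", "c"), times = c(12, 15, 9)))
  y <- rnorm(36, mean = c(a = 0, b = 0.8, c = -0.4)[g])
  res <- oneway_anova(y, g)
  oracle <- anova(aov(y ~ g))
  expect_equal(res$ss_num, oracle["g", "Sum Sq"], tolerance = 1e-10)
  expect_equal(res$ss_den, oracle["Residuals", "Sum Sq"], tolerance = 1e-10)
  expect_equal(res$f, oracle["g", "F value"], tolerance = 1e-10)
  expect_equal(res$p, oracle["g", "Pr(>F)"], tolerance = 1e-10)
  # Exact decomposition and the one-way eta2 identity.
  ss_total <- sum((y - mean(y)) ^ 2)
  expect_equal(res$ss_num + res$ss_den, ss_total, tolerance = 1e-9)
  expect_equal(res$eta2_g, res$ss_num / ss_total, tolerance = 1e-12)

  # Identical constants: F = 0, eta2 = 0.
  zero <- oneway_anova(rep(5, 10), rep(c("a", "b"), 5))
  expect_equal(zero$f, 0)
  expect_equal(zero$eta2_g, 0)
  expect_error(oneway_anova(c(1, 2, 3), c("a", "a", "b")), "b")
})

test_that("published sums of squares reproduce the reported F and eta2g", {
  fcq <- anova_from_ss(2017.62, 16619.16, 2, 111)
  expect_equal(round(fcq$f, 2), 6.74)
  expect_equal(round(fcq$eta2_g, 2), 0.11)
  expect_lt(fcq$p, 0.05)
  sees <- anova_from_ss(2.08, 29.29, 2, 111)
  expect_equal(round(sees$f, 2), 3.94)
})

test_that("Tukey HSD matches stats::TukeyHSD and a permutation oracle", {
  set.seed(77)
  g <- factor(rep(c("g1", "g2", "g3"), times = c(8, 10, 7)))
  y <- rnorm(25, mean = c(g1 = 0, g2 = 1.5, g3 = 0.2)[g])
  mine <- tukey_hsd(y, g)
  oracle <- TukeyHSD(aov(y ~ g))$g
  expect_equal(mine$delta, unname(oracle[, "diff"]), tolerance = 1e-8)
  expect_equal(mine$p, unname(oracle[, "p adj"]), tolerance = 1e-8)
  expect_equal(mine$lwr, unname(oracle[, "lwr"]), tolerance = 1e-8)
  expect_equal(mine$upr, unname(oracle[, "upr"]), tolerance = 1e-8)

  # Two identical groups: delta 0, p = 1.
  same <- tukey_hsd(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1, tolerance = 1e-10)

  # Antisymmetry of the delta_(b-a) convention under relabelling.
  flipped <- tukey_hsd(y, factor(g, levels = c("g3", "g2", "g1")))
  d_12 <- mine$delta[mine$contrast == "g2-g1"]
  d_21 <- flipped$delta[flipped$contrast == "g1-g2"]
  expect_equal(d_12, -d_21)

  # Means 0/0/10 at n = 5: 3-vs-1 significant, 2-vs-1 not; checked against
  # a permutation oracle on the mean difference.
  set.seed(91)
  g2 <- factor(rep(c("g1", "g2", "g3"), each = 5))
  y2 <- rnorm(15, mean = c(0, 0, 10)[as.integer(g2)])
  tk <- tukey_hsd(y2, g2)
  expect_lt(tk$p[tk$contrast == "g3-g1"], 0.05)
  expect_gt(tk$p[tk$contrast == "g2-g1"], 0.05)
  perm_p <- function(a, b, n_perm = 1e5) {
    v <- c(a, b); na <- length(a)
    obs <- abs(mean(b) - mean(a))
    hits <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(length(v), na)
      if (abs(mean(v[-idx]) - mean(v[idx])) >= obs - 1e-12) hits <- hits + 1L
    }
    hits / n_perm
  }
  expect_lt(perm_p(y2[g2 == "g1"], y2[g2 == "g3"]), 0.05)
  expect_gt(perm_p(y2[g2 == "g1"], y2[g2 == "g2"]), 0.05)
})

test_that("the exact r x c Fisher test enumerates the full null", {
  # The 3x2 gender-by-cluster table: p = .019 at three decimals.
  tab <- rbind(c(41, 12), c(34, 1), c(20, 6))
  expect_equal(round(fisher_exact_rxc(tab), 3), 0.019)

  # Both margin-consistent 2x2 tables are equally likely.
  expect_equal(fisher_exact_rxc(rbind(c(1, 0), c(0, 1))), 1)

  # Total enumerated mass is 1.
  det <- fisher_exact_rxc(tab, details = TRUE)
  expect_equal(det$total_mass, 1, tolerance = 1e-10)

  # Random 2x2 tables agree with the closed-form hypergeometric rule and
  # with the fisher.test oracle.
  set.seed(13)
  for (i in 1:15) {
    t2 <- matrix(rpois(4, 6), 2)
    if (any(rowSums(t2) == 0) || any(colSums(t2) == 0)) next
    p_mine <- fisher_exact_rxc(t2)
    m <- sum(t2[1, ]); n <- sum(t2[2, ]); k <- sum(t2[, 1])
    x <- t2[1, 1]
    dens <- dhyper(max(0, k - n):min(k, m), m, n, k)
    p_closed <- sum(dens[dens <= dhyper(x, m, n, k) * (1 + 1e-7)])
    expect_equal(p_mine, p_closed, tolerance = 1e-12)
    expect_equal(p_mine, fisher.test(t2)$p.value, tolerance = 1e-9)
  }
  # r x c agreement with the oracle on the study-shaped table.
  expect_equal(fisher_exact_rxc(tab), fisher.test(tab)$p.value,
               tolerance = 1e-9)
})

test_that("Pearson chi-squared follows the hand formula", {
  # Hand arithmetic: all expected cells 15, statistic 4 * 25 / 15.
  t22 <- rbind(c(10, 20), c(20, 10))
  res <- pearson_chisq(t22)
  expect_equal(res$statistic, 4 * 25 / 15)
  expect_equal(res$p, chisq.test(t22, correct = FALSE)$p.value,
               tolerance = 1e-12)
  # A 3x2 table has df = 2.
  t32 <- rbind(c(10, 9), c(12, 11), c(8, 9))
  expect_equal(pearson_chisq(t32)$df, 2)
  # Perfect proportionality: statistic 0, p = 1.
  prop <- outer(c(10, 20), c(3, 7)) / 10
  res0 <- pearson_chisq(prop)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)
  expect_error(pearson_chisq(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("null ANOVA p-values are uniform over simulated trait tables", {
  set.seed(2024)
  ps <- vapply(1:1000, function(i) {
    y <- rnorm(60)
    oneway_anova(y, rep(1:3, each = 20))$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("the cluster characterisation wrapper assembles all tests", {
  truth <- list(labels = setNames(sample(rep(1:3, each = 15)),
                                  sprintf("P%02d", 1:45)),
                trait_means = rbind(c(40, 3), c(50, 3.3), c(35, 2.7)),
                gender_probs = rbind(c(0.7, 0.3), c(0.95, 0.05),
                                     c(0.7, 0.3)))
  tr <- simulate_traits(truth, noise_sd = c(5, 0.5), seed = 3)
  tr$trait_1[4] <- NA  # listwise deletion per test
  res <- characterize_clusters(tr)
  expect_equal(res$anova$outcome, c("trait_1", "trait_2"))
  a1 <- oneway_anova(tr$trait_1, tr$cluster)
  expect_equal(res$anova$f[1], a1$f)
  expect_equal(nrow(res$tukey$trait_1), 3)
  expect_equal(res$categorical$gender$test, "fisher")
  expect_equal(res$categorical$gender$p,
               fisher_exact_rxc(table(tr$cluster, tr$gender)))
})
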