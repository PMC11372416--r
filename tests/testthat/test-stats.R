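test_that("ANOVA and eta-squared match the explicit SS decomposition", {
  g <- rep(c("a", "b", "c"), each = 4)
  same <- rep(c(1, 2, 3, 4), 3)
  a0 <- anova_eta2(same, g)
  expect_equal(a0$F, 0)
  expect_equal(a0$eta2, 0)
  sep <- c(0, 0, 1, 1, 2, 2)
  a1 <- suppressWarnings(anova_eta2(sep, rep(c("a", "b", "c"), each = 2)))
  expect_equal(a1$eta2, 1)
  set.seed(1)
  v <- rnorm(30); gg <- sample(c("x", "y", "z"), 30, TRUE)
  got <- anova_eta2(v, gg)
  ora <- oracle_anova(v, gg)
  expect_equal(got$F, ora$F, tolerance = 1e-10)
  expect_equal(got$eta2, ora$eta2, tolerance = 1e-10)
  expect_equal(got$p, ora$p, tolerance = 1e-10)
  expect_equal(got$df, ora$df)
  expect_error(anova_eta2(v, rep("x", 30)), "2 non-empty")
})

test_that("pooled t-test ties to Cohen's d and the F = t^2 identity", {
  set.seed(2)
  a <- rnorm(2000, 1); b <- rnorm(2000, 0)
  tt <- ttest_cohend(a, b)
  expect_equal(tt$d, 1, tolerance = 0.15)
  expect_equal(tt$df, 3998)
  same <- rnorm(10)
  t0 <- ttest_cohend(same, same)
  expect_equal(t0$t, 0)
  expect_equal(t0$d, 0)
  an <- anova_eta2(c(a, b), rep(c("A", "B"), c(2000, 2000)))
  expect_equal(an$F, tt$t^2, tolerance = 1e-9)
  # eta2 = t^2 / (t^2 + df) for two groups
  expect_equal(an$eta2, tt$t^2 / (tt$t^2 + tt$df), tolerance = 1e-9)
  expect_error(ttest_cohend(c(1, 1), c(1, 1)), "zero pooled")
})

test_that("BH control matches the step-up scan and dominates Bonferroni", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  r <- bh_fdr(p, 0.05)
  expect_true(all(r$rejected))
  expect_equal(r$rejected, oracle_bh_reject(p, 0.05))
  r1 <- bh_fdr(rep(1, 5), 0.05)
  expect_false(any(r1$rejected))
  expect_equal(r1$q, rep(1, 5))
  r2 <- bh_fdr(0.04, 0.05)
  expect_true(r2$rejected)
  expect_equal(r2$q, 0.04)
  expect_error(bh_fdr(c(0.5, 1.2)), "outside")
  set.seed(3)
  for (i in 1:20) {
    ps <- runif(15)^2
    expect_equal(bh_fdr(ps, 0.05)$rejected, oracle_bh_reject(ps, 0.05))
    bonf <- ps <= 0.05 / length(ps)
    expect_true(all(bh_fdr(ps, 0.05)$rejected[bonf]))
    expect_true(all(bh_fdr(ps, 0.05)$q >= ps - 1e-12))
  }
})

test_that("Fisher exact matches hypergeometric enumeration", {
  f <- fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))
  expect_equal(f$p, oracle_fisher_p(matrix(c(5, 0, 0, 5), 2)),
               tolerance = 1e-9)
  expect_true(is.infinite(f$odds_ratio))
  f2 <- fisher_exact_2x2(matrix(2, 2, 2))
  expect_equal(f2$odds_ratio, 1)
  expect_equal(f2$p, 1)
  set.seed(4)
  for (i in 1:15) {
    tab <- matrix(rpois(4, 3), 2)
    if (sum(tab) == 0 || sum(tab) > 20) next
    expect_equal(fisher_exact_2x2(tab)$p, oracle_fisher_p(tab),
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)),
               "non-negative")
})

test_that("feature ranking surfaces the injected asymmetry and is order-invariant", {
  set.seed(5)
  n <- 36
  lat <- rep(c("left", "right", "bilateral"), each = 12)
  mu <- c(left = 0.5, right = -0.5, bilateral = 0)[lat]
  ai <- cbind(matrix(rnorm(n * 8, 0, 0.4), n),
              spike = mu + rnorm(n, 0, 0.15))
  colnames(ai) <- c(paste0("noise", 1:8), "spikes__bb__car__sleep")
  rk <- rank_features(ai, lat)
  expect_equal(rk$feature[1], "spikes__bb__car__sleep")
  expect_true(rk$significant[1])
  perm <- sample(ncol(ai))
  rk2 <- rank_features(ai[, perm], lat)
  expect_equal(rk2$feature, rk$feature)
  expect_equal(rk2$eta2, rk$eta2)
})

test_that("null AI cohorts keep per-feature false positives near alpha", {
  set.seed(6)
  n <- 30; nf <- 60; reps <- 8
  rej <- replicate(reps, {
    ai <- matrix(rnorm(n * nf), n)
    lat <- sample(rep(c("left", "right", "bilateral"), each = 10))
    mean(vapply(seq_len(nf), function(j)
      anova_eta2(ai[, j], lat)$p < 0.05, TRUE))
  })
  # binomial tolerance around alpha = 0.05
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})

test_that("outcome concordance picks the surgery-side model and separates outcomes", {
  surg <- c("left", "left", "right", "right", "none",
            "left", "right", "left", "right", "left")
  p_left <- c(0.9, 0.8, 0.3, 0.2, 0.5, 0.85, 0.25, 0.3, 0.4, 0.75)
  p_right <- c(0.1, 0.2, 0.85, 0.9, 0.5, 0.15, 0.8, 0.6, 0.3, 0.2)
  engel <- c(1, 1, 1, 1, NA, 1, 1, 3, 4, 1)
  ilae <- c(1, 2, 1, 2, NA, 1, 2, 4, 5, 2)
  oc <- outcome_concordance(surg, engel, ilae, p_left, p_right)
  expect_equal(oc$concordant[1], 0.9)      # left surgery -> left model
  expect_equal(oc$concordant[3], 0.85)     # right surgery -> right model
  expect_true(is.na(oc$concordant[5]))     # unoperated
  expect_gt(oc$engel$mean_a, oc$engel$mean_b)
  expect_gt(oc$ilae$mean_a, oc$ilae$mean_b)
  expect_error(outcome_concordance(surg, rep(1, 10), rep(1, 10), p_left,
                                   p_right), "per outcome group")
  expect_error(outcome_concordance(rep("none", 4), engel[1:4], ilae[1:4],
                                   p_left[1:4], p_right[1:4]),
               "no operated")
})

test_that("outcome logistic LOO separates when the predictor separates", {
  conc <- c(0.9, 0.85, 0.8, 0.75, 0.2, 0.25, 0.3, 0.15)
  good <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  r <- outcome_logistic_loocv(conc, good)
  expect_equal(r$auc, 1)
  expect_equal(length(r$probabilities), 8)
  # permuted predictor: chance-level over draws
  set.seed(7)
  aucs <- replicate(12, outcome_logistic_loocv(sample(conc), good)$auc)
  expect_lt(abs(mean(aucs) - 0.5), 0.25)
  r4 <- outcome_logistic_loocv(c(0.8, 0.7, 0.3, 0.4),
                               c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(length(r4$probabilities), 4)
  expect_error(outcome_logistic_loocv(conc, rep(TRUE, 8)), "single")
})
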