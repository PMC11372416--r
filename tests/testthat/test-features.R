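fs_t <- 200
tvec <- seq(1 / fs_t, 60, by = 1 / fs_t)

test_that("line length matches its definition and scales linearly", {
  expect_equal(line_length(c(0, 1, 3, 2)), 4)
  expect_equal(line_length(rep(2.5, 100)), 0)
  set.seed(1)
  x <- rnorm(500)
  expect_equal(line_length(3 * x), 3 * line_length(x))
  expect_equal(line_length(x, fs = 200), line_length(x) /
                 ((499 / 200) / 60))
  expect_error(line_length(1), "2 samples")
})

test_that("band power concentrates where the signal lives", {
  x10 <- sin(2 * pi * 10 * tvec)
  expect_gte(bandpower(x10, "alpha", fs_t) / bandpower(x10, "bb", fs_t),
             0.9)
  expect_equal(bandpower(numeric(12000), "delta", fs_t), 0)
  expect_error(bandpower(x10, c(10, 150), fs_t), "Nyquist")
  # white noise: band power proportional to bandwidth (Monte-Carlo)
  set.seed(12)
  x <- rnorm(fs_t * 120)
  tot <- bandpower(x, c(0.5, 80), fs_t)
  for (b in c("theta", "alpha", "beta", "gamma")) {
    e <- canonical_bands()[[b]]
    expect_equal(bandpower(x, b, fs_t) / tot, (e[2] - e[1]) / 79.5,
                 tolerance = 0.1)
  }
})

test_that("spectral entropy spans noise-to-tone extremes", {
  p_uniform <- rep(0.25, 40)
  expect_equal(interlat:::spectral_entropy_from_psd(p_uniform), 1)
  set.seed(3)
  expect_gte(spectral_entropy(rnorm(fs_t * 60), fs_t), 0.9)
  expect_lte(spectral_entropy(sin(2 * pi * 10 * tvec), fs_t), 0.3)
  expect_true(is.na(spectral_entropy(numeric(4000), fs_t)))
})

test_that("pearson_sq is squared correlation with degenerate guard", {
  set.seed(4)
  x <- rnorm(5000)
  expect_equal(pearson_sq(x, x), 1)
  expect_equal(pearson_sq(x, -x), 1)
  expect_lt(pearson_sq(x, rnorm(5000)), 0.05)
  expect_true(is.na(pearson_sq(x, rep(1, 5000))))
})

test_that("cross correlation finds shifts and matches the brute-force scan", {
  set.seed(5)
  x <- rnorm(2000)
  y <- c(numeric(6), x[1:1994])
  expect_equal(cross_corr(x, y, 40), 1, tolerance = 1e-6)
  expect_equal(cross_corr(x, x, 40), 1)
  for (i in 1:3) {
    a <- rnorm(400); b <- rnorm(400)
    expect_equal(cross_corr(a, b, 25), oracle_cross_corr(a, b, 25),
                 tolerance = 1e-10)
  }
  expect_error(cross_corr(x, y, 2000), "below")
})

test_that("coherence behaves across identity, noise and SNR gradations", {
  set.seed(6)
  x <- rnorm(fs_t * 60)
  for (b in c("delta", "alpha", "gamma", "bb"))
    expect_equal(coherence(x, x, b, fs_t), 1, tolerance = 1e-9)
  # independent noise: bias ~ 1 / #averages
  expect_lt(coherence(x, rnorm(fs_t * 60), "alpha", fs_t), 0.1)
  # added noise pulls coherence strictly inside (0, 1), monotonically
  c1 <- coherence(x, x + 0.5 * rnorm(length(x)), "alpha", fs_t)
  c2 <- coherence(x, x + 2 * rnorm(length(x)), "alpha", fs_t)
  expect_true(c2 < c1 && c1 < 1 && c2 > 0)
})

test_that("PLV is exact for locked phases and Rayleigh-small for noise", {
  x <- sin(2 * pi * 10 * tvec)
  expect_equal(plv(x, x, "alpha", fs_t), 1, tolerance = 1e-9)
  x90 <- sin(2 * pi * 10 * tvec + pi / 2)
  expect_equal(plv(x, x90, "alpha", fs_t), 1, tolerance = 1e-3)
  expect_true(is.na(plv(x, numeric(length(x)), "alpha", fs_t)))
  # independent uniform phases: E|mean phasor| = sqrt(pi) / (2 sqrt(T))
  set.seed(7)
  T <- 4000
  vals <- replicate(30, interlat:::plv_from_phases(
    runif(T, -pi, pi), runif(T, -pi, pi)))
  expect_equal(mean(vals), sqrt(pi) / (2 * sqrt(T)), tolerance = 0.15)
})

test_that("relative entropy is zero at identity, symmetric, and matches direct KL", {
  set.seed(8)
  x <- rnorm(5000)
  expect_equal(relative_entropy(x, x, "bb", fs_t), 0)
  y <- rnorm(5000, 1, 2)
  expect_equal(relative_entropy(x, y, "alpha", fs_t),
               relative_entropy(y, x, "alpha", fs_t))
  # discretized-Gaussian oracle on the histogram core
  xf <- rnorm(3000); yf <- rnorm(3000, 0.8, 1.3)
  got <- interlat:::relative_entropy_hist(xf, yf, bins = 30,
                                          smoothing = 1e-6)
  edges <- seq(min(c(xf, yf)), max(c(xf, yf)), length.out = 31)
  cx <- as.numeric(table(cut(xf, edges, include.lowest = TRUE)))
  cy <- as.numeric(table(cut(yf, edges, include.lowest = TRUE)))
  p <- (cx + 1e-6) / sum(cx + 1e-6); q <- (cy + 1e-6) / sum(cy + 1e-6)
  expect_equal(got, oracle_sym_kl(p, q), tolerance = 1e-9)
})

test_that("bounded features respect bounds on random inputs", {
  set.seed(9)
  for (i in 1:5) {
    x <- rnorm(3000) + sin(2 * pi * runif(1, 1, 30) * (1:3000) / fs_t)
    y <- rnorm(3000)
    expect_true(pearson_sq(x, y) >= 0 && pearson_sq(x, y) <= 1)
    expect_true(cross_corr(x, y, 30) >= 0 && cross_corr(x, y, 30) <= 1)
    b <- sample(c("delta", "alpha", "beta"), 1)
    cc <- coherence(x, y, b, fs_t)
    expect_true(cc >= 0 && cc <= 1)
    pp <- plv(x, y, b, fs_t)
    expect_true(pp >= 0 && pp <= 1)
    expect_gte(relative_entropy(x, y, b, fs_t), 0)
    se <- spectral_entropy(x, fs_t)
    expect_true(se >= 0 && se <= 1)
  }
})

test_that("amplitude scaling leaves normalized pair features unchanged", {
  set.seed(10)
  x <- rnorm(4000); y <- 0.5 * x + rnorm(4000)
  a <- 17.3
  expect_equal(pearson_sq(a * x, a * y), pearson_sq(x, y))
  expect_equal(cross_corr(a * x, a * y, 20), cross_corr(x, y, 20))
  expect_equal(coherence(a * x, a * y, "alpha", fs_t),
               coherence(x, y, "alpha", fs_t), tolerance = 1e-9)
  expect_equal(plv(a * x, a * y, "alpha", fs_t), plv(x, y, "alpha", fs_t),
               tolerance = 1e-9)
})
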