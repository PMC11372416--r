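toy_ai <- function(n = 24, seed = 1) {
  set.seed(seed)
  lat <- rep(c("left", "right", "bilateral"), length.out = n)
  mu <- c(left = 0.6, right = -0.6, bilateral = 0)[lat]
  m <- cbind(spike = mu + rnorm(n, 0, 0.2),
             noise1 = rnorm(n), noise2 = rnorm(n))
  list(ai = m, lat = lat)
}

test_that("imputation and standardization learn only from training data", {
  tr <- rbind(c(1, 5), c(NA, 7), c(3, 9))
  colnames(tr) <- c("a", "b")
  ap <- rbind(c(NA, NA))
  colnames(ap) <- c("a", "b")
  si <- standardize_impute(tr, ap)
  expect_equal(si$medians, c(a = 2, b = 7))  # train median fills missing
  # apply-set missing filled with the TRAINING median, standardized
  expect_equal(unname(si$apply[1, ]), c(0, 0))
  # constant column standardized to zeros and flagged
  tr2 <- cbind(a = c(1, 2, 3), b = c(4, 4, 4))
  si2 <- standardize_impute(tr2)
  expect_true(si2$zero_var["b"])
  expect_equal(unname(si2$train[, "b"]), c(0, 0, 0))
  expect_warning(standardize_impute(cbind(a = c(1, 2), b = c(NA, NA))),
                 "all-missing")
})

test_that("PCA retention matches the eigenvalue oracle", {
  set.seed(2)
  X <- matrix(rnorm(40 * 6), 40)
  X[, 4] <- X[, 1] * 2  # redundant direction
  lat <- rep(c("left", "right"), 20)
  m <- fit_laterality(X, lat, "left", var_explained = 0.95)
  Z <- standardize_impute(X)$train
  ev <- sort(eigen(crossprod(Z) / (nrow(Z) - 1))$values,
             decreasing = TRUE)
  k_oracle <- which(cumsum(ev) / sum(ev) >= 0.95)[1]
  expect_equal(m$k, k_oracle)
  expect_gte(m$explained, 0.95)
})

test_that("lasso solver agrees with the proximal-gradient reference", {
  set.seed(3)
  for (i in 1:5) {
    X <- matrix(rnorm(15), 5, 3)
    y <- rbinom(5, 1, 0.5)
    if (length(unique(y)) < 2) y <- c(0, 1, y[3:5])
    w <- runif(5, 0.5, 2)
    f <- lasso_logistic(X, y, lambda = 1 / 5, weights = w)
    th <- oracle_lasso(X, y, 1 / 5, w)
    expect_equal(c(f$intercept, f$beta), unname(th), tolerance = 1e-6)
  }
  # infinite-penalty limit: slopes zero, intercept = weighted base-rate odds
  y <- c(1, 0, 0, 1, 1, 0, 0, 0)
  f <- lasso_logistic(matrix(rnorm(16), 8), y, lambda = 1e9)
  expect_equal(f$beta, c(0, 0))
  expect_equal(f$intercept, qlogis(mean(y)), tolerance = 1e-6)
})

test_that("separable toy data reach training AUC 1 and sane predictions", {
  d <- toy_ai(24, seed = 4)
  m <- fit_laterality(d$ai, d$lat, "left")
  p <- predict(m, d$ai)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(roc_auc(as.integer(d$lat == "left"), p)$auc, 1)
  imp <- feature_importance(m)
  expect_equal(length(imp), 3)
  # hand-computed matrix identity
  expect_equal(unname(imp), unname(drop(m$rotation %*% m$beta)),
               tolerance = 1e-12)
  expect_output(print(m), "laterality_model")
  expect_error(fit_laterality(d$ai, rep("left", 24), "left"),
               "single-class")
})

test_that("AUC equals pair counting and respects monotone invariance", {
  lab <- c(1, 0, 1, 0)
  sc <- c(0.9, 0.8, 0.4, 0.3)
  expect_equal(roc_auc(lab, sc)$auc, 0.75)
  expect_equal(roc_auc(lab, sc)$auc, oracle_auc(lab, sc))
  expect_equal(roc_auc(c(1, 1, 0), c(0.9, 0.8, 0.1))$auc, 1)
  expect_equal(roc_auc(c(1, 1, 0), c(0.1, 0.2, 0.9))$auc, 0)
  set.seed(5)
  lab2 <- rbinom(30, 1, 0.5); sc2 <- rnorm(30)
  expect_equal(roc_auc(lab2, sc2)$auc, oracle_auc(lab2, sc2))
  expect_equal(roc_auc(lab2, plogis(3 * sc2 - 1))$auc,
               roc_auc(lab2, sc2)$auc)  # monotone transform
  expect_error(roc_auc(c(1, 1), c(0.1, 0.2)), "single class")
})

test_that("operating point maximizes Youden's J like the brute-force scan", {
  set.seed(6)
  y <- rbinom(40, 1, 0.4)
  s <- y * 0.3 + runif(40)
  op <- operating_point(y, s)
  # exhaustive midpoint scan
  u <- sort(unique(s))
  cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  J <- vapply(cand, function(t) mean(s[y == 1] >= t) +
                mean(s[y == 0] < t) - 1, 1)
  expect_equal(op$youden, max(J), tolerance = 1e-12)
  expect_equal(op$balanced_accuracy,
               (op$sensitivity + op$specificity) / 2)
  expect_equal(sum(op$confusion), 40)
  # known arithmetic: sens 1.0, spec 0.5 -> balanced accuracy 0.75
  expect_equal((1 + 0.5) / 2, 0.75)
  opp <- operating_point(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(opp$balanced_accuracy, 1)
})

test_that("LOO CV refits the pipeline per fold without leakage", {
  d <- toy_ai(21, seed = 7)
  cv <- loocv_laterality(d$ai, d$lat, "left")
  expect_equal(length(cv$probabilities), 21)
  expect_true(all(cv$probabilities >= 0 & cv$probabilities <= 1))
  expect_gte(cv$auc, 0.9)
  # no leakage: fold i's pipeline is fit strictly without patient i, so its
  # held-out probability equals an explicit refit-and-predict
  for (i in c(4, 11)) {
    m_i <- fit_laterality(d$ai[-i, ], d$lat[-i], "left")
    expect_equal(cv$probabilities[i],
                 unname(predict(m_i, d$ai[i, , drop = FALSE])),
                 tolerance = 1e-10)
  }
  # and corrupting patient i's AI changes no other fold's training labels
  # or imputation source except through its own row's presence
  ai2 <- d$ai
  ai2[4, ] <- d$ai[4, ] + 1e-9   # infinitesimal perturbation of one row
  cv2 <- suppressWarnings(loocv_laterality(ai2, d$lat, "left"))
  expect_equal(cv2$probabilities[4], cv$probabilities[4], tolerance = 1e-4)
  # minimal n = 3 contract
  cv3 <- suppressWarnings(loocv_laterality(d$ai[1:3, ], d$lat[1:3],
                                           "left"))
  expect_equal(length(cv3$probabilities), 3)
  expect_error(loocv_laterality(d$ai[1:2, ], d$lat[1:2], "left"), "n >= 3")
})

test_that("external validation freezes the internal pipeline", {
  d <- toy_ai(30, seed = 8)
  cv <- loocv_laterality(d$ai, d$lat, "left")
  m <- fit_laterality(d$ai, d$lat, "left", threshold = cv$threshold)
  ext <- toy_ai(24, seed = 9)
  ev <- external_validate(m, ext$ai, ext$lat)
  expect_gte(ev$auc, 0.9)
  expect_equal(sum(ev$confusion), 24)
  # flipping hemispheres (negated AI) and labels gives identical metrics
  lat_fl <- chartr("lr", "rl", sub("left", "tmp", ext$lat))
  lat_fl <- ifelse(ext$lat == "left", "right",
                   ifelse(ext$lat == "right", "left", "bilateral"))
  m_r <- fit_laterality(-d$ai, ifelse(d$lat == "left", "right",
                                      ifelse(d$lat == "right", "left",
                                             "bilateral")),
                        "right", threshold = cv$threshold)
  ev_fl <- external_validate(m_r, -ext$ai, lat_fl)
  expect_equal(ev_fl$auc, ev$auc, tolerance = 1e-9)
  expect_equal(ev_fl$balanced_accuracy, ev$balanced_accuracy,
               tolerance = 1e-9)
  expect_error(external_validate(m, d$ai[0, , drop = FALSE], character(0)),
               "empty")
})

test_that("binarized spike AI follows the sign coding and tie rule", {
  expect_equal(binarize_spike_ai(c(0.3, -0.2)), c(1L, 0L))
  expect_warning(z <- binarize_spike_ai(0), "tie")
  expect_equal(z, 0L)
  expect_true(is.na(binarize_spike_ai(NA)))
})

test_that("the calculator reports AI and both model probabilities", {
  d <- toy_ai(30, seed = 10)
  m1 <- matrix(d$ai[, 1], ncol = 1,
               dimnames = list(NULL, "spikes__bb__car__sleep"))
  left_m <- fit_laterality(m1, d$lat, "left")
  right_m <- fit_laterality(m1, d$lat, "right")
  out <- predict_calculator(10, 2.5, left_m, right_m)
  expect_equal(out$ai, 0.6)
  expect_equal(predict_calculator(10, 2, left_m, right_m)$ai, 8 / 12)
  expect_true(out$p_left > 0 && out$p_left < 1)
  eq <- predict_calculator(3, 3, left_m, right_m)
  expect_equal(eq$ai, 0)
  expect_error(predict_calculator(0, 0, left_m, right_m), "both")
  # monotone in AI when the fitted slope is positive
  imp <- feature_importance(left_m)
  ps <- vapply(seq(-0.9, 0.9, by = 0.3), function(a)
    predict(left_m, matrix(a, ncol = 1,
                           dimnames = list(NULL,
                                           "spikes__bb__car__sleep"))), 1)
  if (imp[1] > 0) expect_true(all(diff(ps) >= 0))
  # serialization round-trip preserves predictions
  path <- tempfile(fileext = ".json")
  write_laterality_model(left_m, path)
  back <- read_laterality_model(path)
  expect_equal(predict(back, m1), predict(left_m, m1), tolerance = 1e-12)
})

test_that("duration subsampling is seeded, capped, and exact at full draw", {
  set.seed(11)
  counts <- lapply(1:12, function(i) {
    lat <- rep(c("left", "right", "bilateral"), 4)[i]
    rate <- if (lat == "left") c(8, 8, 2, 2) else
      if (lat == "right") c(2, 2, 8, 8) else c(8, 8, 8, 8)
    m <- matrix(rpois(4 * 6, rate), 4, 6)
    attr(m, "side") <- c("L", "L", "R", "R")
    m
  })
  lats <- rep(c("left", "right", "bilateral"), 4)
  full <- duration_subsample_experiment(counts, lats, minutes = 6,
                                        reps = 3, seed = 2)
  # degenerate draw: every rep uses all segments, sd is 0
  expect_equal(full$sd, 0)
  curve1 <- duration_subsample_experiment(counts, lats, minutes = c(2, 6),
                                          reps = 2, seed = 3)
  curve2 <- duration_subsample_experiment(counts, lats, minutes = c(2, 6),
                                          reps = 2, seed = 3)
  expect_identical(curve1, curve2)      # seeded reproducibility
  expect_warning(duration_subsample_experiment(counts, lats, minutes = 99,
                                               reps = 1, seed = 4),
                 "capped")
})
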