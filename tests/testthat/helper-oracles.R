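# Independent reference implementations used to cross-check the package's
# estimators. Each is deliberately written on a different code path than the
# implementation it validates.

# AUC by exhaustive pair counting (ties count 1/2)
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Benjamini-Hochberg by the literal step-up scan over i * alpha / m
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * alpha / m) k <- i
  rejected <- rep(FALSE, m)
  if (k > 0) rejected[o[seq_len(k)]] <- TRUE
  rejected
}

# one-way ANOVA by explicit sum-of-squares decomposition
oracle_anova <- function(values, groups) {
  g <- split(values, groups)
  g <- g[vapply(g, length, 1) > 0]
  gm <- mean(unlist(g))
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - gm)^2, 1))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), 1))
  df1 <- length(g) - 1
  df2 <- length(unlist(g)) - length(g)
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, eta2 = ssb / (ssb + ssw), df = c(df1, df2),
       p = pf(F, df1, df2, lower.tail = FALSE))
}

# Fisher exact two-sided p by full hypergeometric enumeration of tables with
# the observed margins
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(support, function(a)
    choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1), 1)
  obs <- probs[support == tab[1, 1]]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# weighted L1 logistic by proximal gradient descent (same objective as
# lasso_logistic: weights normalized to sum 1, intercept unpenalized)
oracle_lasso <- function(X, y, lambda, w = NULL, iters = 2e5) {
  n <- nrow(X); p <- ncol(X)
  w <- if (is.null(w)) rep(1, n) else w
  w <- w / sum(w)
  Xb <- cbind(1, X)
  th <- numeric(p + 1)
  L <- 0.25 * max(eigen(crossprod(Xb * sqrt(w)))$values) + 1e-9
  for (i in seq_len(iters)) {
    eta <- drop(Xb %*% th)
    mu <- 1 / (1 + exp(-eta))
    g <- drop(crossprod(Xb, w * (mu - y)))
    th_new <- th - g / L
    th_new[-1] <- sign(th_new[-1]) * pmax(abs(th_new[-1]) - lambda / L, 0)
    if (max(abs(th_new - th)) < 1e-12) return(th_new)
    th <- th_new
  }
  th
}

# per-lag Pearson cross-correlation by a literal double window scan
oracle_cross_corr <- function(x, y, max_lag) {
  n <- length(x); best <- NA_real_
  for (l in -max_lag:max_lag) {
    if (l >= 0) { xs <- x[1:(n - l)]; ys <- y[(1 + l):n] }
    else { xs <- x[(1 - l):n]; ys <- y[1:(n + l)] }
    r <- abs(cor(xs, ys))
    if (is.na(best) || r > best) best <- r
  }
  best
}

# symmetrized KL between two discretized distributions by direct summation
oracle_sym_kl <- function(p, q) {
  0.5 * (sum(p * log(p / q)) + sum(q * log(q / p)))
}
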