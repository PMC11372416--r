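#' Weighted L1-penalized logistic regression
#'
#' Minimizes the weighted average negative log-likelihood plus an L1 penalty
#' on the slopes,
#' \deqn{\sum_i \tilde w_i [\log(1 + e^{\eta_i}) - y_i \eta_i] +
#'       \lambda \|\beta\|_1,}
#' with the observation weights normalized to sum to one and the intercept
#' unpenalized. Solved by iteratively reweighted least squares with
#' cyclic coordinate descent and soft-thresholding; fully deterministic.
#'
#' @param x numeric predictor matrix (n x p), used as-is (no internal
#'   standardization).
#' @param y binary 0/1 response.
#' @param lambda L1 penalty (the laterality models use `1/N` with `N` the
#'   training sample size).
#' @param weights observation weights (default equal); internally normalized
#'   to sum 1.
#' @param tol convergence tolerance on the maximal coefficient change.
#' @param maxit iteration cap.
#' @return list with `intercept`, `beta` (length p), `lambda`, `iterations`,
#'   `converged`.
#' @export
lasso_logistic <- function(x, y, lambda, weights = NULL, tol = 1e-8,
                           maxit = 1e5) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  y <- as.numeric(y)
  stopifnot(length(y) == n, all(y %in% c(0, 1)))
  w <- weights %||% rep(1, n)
  w <- w / sum(w)
  b0 <- 0; beta <- numeric(p)
  eta <- rep(b0, n)
  it <- 0; converged <- FALSE
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  while (it < maxit) {
    it <- it + 1
    mu <- 1 / (1 + exp(-eta))
    mu <- pmin(pmax(mu, 1e-8), 1 - 1e-8)
    wq <- w * mu * (1 - mu)
    z <- eta + (y - mu) / (mu * (1 - mu))
    # one full cycle of coordinate descent on the quadratic approximation
    old <- c(b0, beta)
    r <- z - eta
    b0_new <- b0 + sum(wq * r) / sum(wq)
    r <- r - (b0_new - b0); b0 <- b0_new
    for (j in seq_len(p)) {
      xj <- x[, j]
      denom <- sum(wq * xj^2)
      if (denom <= 0) next
      zj <- sum(wq * xj * (r + xj * beta[j]))
      bj <- soft(zj, lambda) / denom
      if (bj != beta[j]) {
        r <- r - xj * (bj - beta[j])
        beta[j] <- bj
      }
    }
    eta <- b0 + drop(x %*% beta)
    if (max(abs(c(b0, beta) - old)) < tol) { converged <- TRUE; break }
  }
  list(intercept = b0, beta = beta, lambda = lambda, iterations = it,
       converged = converged)
}
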