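#' One-way ANOVA with eta-squared effect size
#'
#' Fixed-effects one-way ANOVA across laterality groups;
#' \eqn{\eta^2 = SS_{between}/SS_{total}}. Missing values are dropped.
#'
#' @param values numeric vector.
#' @param groups grouping factor (>= 2 non-empty groups with >= 2 values
#'   each).
#' @return list with `F`, `df` (c(df1, df2)), `p`, `eta2`, `group_means`,
#'   `group_sds`, `n`.
#' @export
anova_eta2 <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  v <- values[keep]; g <- droplevels(factor(groups[keep]))
  if (nlevels(g) < 2) stop("need >= 2 non-empty groups")
  if (any(table(g) < 2)) stop("need >= 2 values per group")
  a <- anova(lm(v ~ g))
  ssb <- a$`Sum Sq`[1]; ssw <- a$`Sum Sq`[2]
  list(F = a$`F value`[1], df = c(a$Df[1], a$Df[2]),
       p = a$`Pr(>F)`[1], eta2 = ssb / (ssb + ssw),
       group_means = tapply(v, g, mean), group_sds = tapply(v, g, sd),
       n = length(v))
}

#' Pooled-variance t-test with Cohen's d
#'
#' Classic two-sample t-test (equal-variance pooling, so the degrees of
#' freedom are the integer \eqn{n_a + n_b - 2});
#' \eqn{d = (\bar a - \bar b)/s_{pooled}}.
#'
#' @param a,b numeric samples (>= 2 each after dropping missing).
#' @param alternative passed to [stats::t.test()].
#' @return list with `t`, `df`, `p`, `d`, `mean_a`, `mean_b`, `sd_a`,
#'   `sd_b`.
#' @export
ttest_cohend <- function(a, b, alternative = "two.sided") {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 values per group")
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) stop("zero pooled variance")
  tt <- t.test(a, b, var.equal = TRUE, alternative = alternative)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = (mean(a) - mean(b)) / sqrt(sp2),
       mean_a = mean(a), mean_b = mean(b), sd_a = sd(a), sd_b = sd(b))
}

#' Benjamini--Hochberg false-discovery-rate control
#'
#' Step-up procedure at level `alpha`; `q` values are the monotone-adjusted
#' p-values.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return list with `q` and logical `rejected`.
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values outside [0, 1]")
  q <- p.adjust(p, method = "BH")
  list(q = q, rejected = !is.na(q) & q <= alpha)
}

#' Rank AI features by laterality effect size
#'
#' Per feature: one-way ANOVA across the three lateralities with
#' \eqn{\eta^2}, BH correction across all testable features, plus pairwise
#' pooled t / Cohen's d for left-versus-bilateral and
#' right-versus-bilateral. Features with fewer than two populated groups are
#' skipped with a note. Rows are ordered by descending \eqn{\eta^2}.
#'
#' @param ai patients x features AI matrix.
#' @param laterality per-patient labels.
#' @param alpha FDR level.
#' @return data.frame with per-feature statistics, ordered by `eta2`.
#' @export
rank_features <- function(ai, laterality, alpha = 0.05) {
  ai <- as.matrix(ai)
  lat <- factor(laterality, levels = c("left", "right", "bilateral"))
  rows <- lapply(colnames(ai) %||% seq_len(ncol(ai)), function(key) {
    v <- ai[, key]
    ok_groups <- sum(tapply(!is.na(v), lat, sum, default = 0) >= 2)
    if (ok_groups < 2) return(NULL)
    an <- tryCatch(anova_eta2(v, lat), error = function(e) NULL)
    if (is.null(an)) return(NULL)
    pair <- function(g1, g2) {
      a <- v[lat == g1 & !is.na(v)]; b <- v[lat == g2 & !is.na(v)]
      if (length(a) < 2 || length(b) < 2) return(c(NA_real_, NA_real_))
      tc <- tryCatch(ttest_cohend(a, b), error = function(e) NULL)
      if (is.null(tc)) c(NA_real_, NA_real_) else c(tc$d, tc$p)
    }
    lb <- pair("left", "bilateral"); rb <- pair("right", "bilateral")
    data.frame(feature = as.character(key), F = an$F, df1 = an$df[1],
               df2 = an$df[2], p = an$p, eta2 = an$eta2, n = an$n,
               d_left_bilateral = lb[1], p_left_bilateral = lb[2],
               d_right_bilateral = rb[1], p_right_bilateral = rb[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) stop("no testable features")
  bh <- bh_fdr(out$p, alpha)
  out$q <- bh$q
  out$significant <- bh$rejected
  out[order(-out$eta2), , drop = FALSE]
}

#' Concordance between model-predicted laterality and surgery side
#'
#' For each operated patient, takes the predicted probability from the model
#' matching the surgery side (the left-versus-rest model for left-sided
#' surgery, right-versus-rest for right), and compares these concordant
#' probabilities between good- and poor-outcome groups (good = Engel 1 /
#' ILAE 1--2 at one year) with a pooled t-test and Cohen's d.
#'
#' @param surgery_side per-patient `"left"`/`"right"`/`"none"`.
#' @param engel,ilae one-year outcome scores (NA when unoperated or without
#'   follow-up).
#' @param p_left,p_right per-patient model probabilities (typically pooled
#'   leave-one-out probabilities of the spike-rate models).
#' @param alternative `"two.sided"` or `"greater"` (good > poor).
#' @return list with the per-patient `concordant` probabilities, `good_engel`
#'   and `good_ilae` flags, and `engel`/`ilae` t-test results.
#' @export
outcome_concordance <- function(surgery_side, engel, ilae, p_left, p_right,
                                alternative = "two.sided") {
  operated <- surgery_side %in% c("left", "right")
  if (!any(operated)) stop("no operated patients")
  conc <- ifelse(surgery_side == "left", p_left, p_right)
  conc[!operated] <- NA
  good_engel <- ifelse(operated & !is.na(engel), engel == 1, NA)
  good_ilae <- ifelse(operated & !is.na(ilae), ilae <= 2, NA)
  cmp <- function(good) {
    if (sum(good %in% TRUE & !is.na(conc)) < 2 ||
        sum(good %in% FALSE & !is.na(conc)) < 2)
      stop("need >= 2 operated patients per outcome group")
    ttest_cohend(conc[good %in% TRUE], conc[good %in% FALSE],
                 alternative = alternative)
  }
  list(concordant = conc, good_engel = good_engel, good_ilae = good_ilae,
       engel = cmp(good_engel), ilae = cmp(good_ilae))
}

#' Leave-one-out logistic prediction of surgical outcome
#'
#' Single-predictor logistic regression of good outcome on the concordant
#' model probability, validated by leave-one-out cross-validation; reports
#' the AUC of the pooled held-out probabilities.
#'
#' @param concordant per-patient concordant model probabilities.
#' @param good logical good-outcome flags.
#' @return list with `probabilities`, `auc`.
#' @export
outcome_logistic_loocv <- function(concordant, good) {
  keep <- !is.na(concordant) & !is.na(good)
  x <- concordant[keep]; y <- as.integer(good[keep])
  n <- length(y)
  if (n < 4) stop("need n >= 4")
  if (length(unique(y)) < 2) stop("single outcome class")
  prob <- vapply(seq_len(n), function(i) {
    fit <- suppressWarnings(glm(y[-i] ~ x[-i], family = binomial()))
    unname(1 / (1 + exp(-(coef(fit)[1] + coef(fit)[2] * x[i]))))
  }, numeric(1))
  list(probabilities = prob, auc = roc_auc(y, prob)$auc, n = n)
}

#' Fisher's exact test for a 2x2 table
#'
#' Conditional (hypergeometric) two-sided exact p-value and the sample odds
#' ratio \eqn{ad/bc} (with the infinite-odds convention for empty cells).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list with `odds_ratio` (sample OR) and `p`.
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == 2)) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  p <- fisher.test(tab)$p.value
  list(odds_ratio = or, p = p)
}
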