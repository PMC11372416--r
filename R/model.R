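#' Bundle a cohort's AI matrix with clinical labels
#'
#' @param ai patients x features AI matrix (canonical column order).
#' @param laterality per-patient SOZ laterality,
#'   `"left"`/`"right"`/`"bilateral"`.
#' @param surgery_side optional, `"left"`/`"right"`/`"none"`.
#' @param engel,ilae optional one-year outcome scores.
#' @param site optional site tag.
#' @return a `cohort_dataset`.
#' @export
cohort_dataset <- function(ai, laterality, surgery_side = NULL,
                           engel = NULL, ilae = NULL, site = NULL) {
  ai <- as.matrix(ai)
  laterality <- as.character(laterality)
  if (length(laterality) != nrow(ai))
    stop("one laterality label per patient required")
  if (!all(laterality %in% c("left", "right", "bilateral")))
    stop("laterality must be left/right/bilateral")
  structure(list(ai = ai, laterality = laterality,
                 surgery_side = surgery_side, engel = engel, ilae = ilae,
                 site = site),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d patients x %d AI features (%s)\n",
              nrow(x$ai), ncol(x$ai),
              paste(names(table(x$laterality)), table(x$laterality),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Median imputation and z-scoring learned on training data
#'
#' Per-column training medians fill missing values in both the training and
#' any apply matrix (never the apply matrix's own statistics, to avoid
#' leakage); columns are then centred and scaled by the training mean and SD.
#' Zero-variance columns are mapped to all-zero and flagged; all-missing
#' training columns are dropped with a warning.
#'
#' @param train training AI matrix.
#' @param apply optional matrix to transform with the training statistics
#'   (columns aligned by name; absent columns are filled with the training
#'   median).
#' @return list with `train`, `apply` (transformed matrices), `medians`,
#'   `center`, `scale`, `zero_var`, `dropped`.
#' @export
standardize_impute <- function(train, apply = NULL) {
  train <- as.matrix(train)
  if (nrow(train) < 2) stop("need at least 2 training patients")
  all_na <- apply(is.na(train), 2, all)
  dropped <- colnames(train)[all_na]
  if (any(all_na)) {
    warning("dropping all-missing training columns: ",
            paste(dropped, collapse = ", "))
    train <- train[, !all_na, drop = FALSE]
  }
  med <- apply(train, 2, median, na.rm = TRUE)
  fill <- function(m) {
    for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- med[j]
    m
  }
  tr <- fill(train)
  ctr <- colMeans(tr)
  scl <- apply(tr, 2, sd)
  zv <- scl == 0
  scl[zv] <- 1
  std <- function(m) {
    m <- sweep(sweep(m, 2, ctr), 2, scl, "/")
    m[, zv] <- 0
    m
  }
  out <- list(train = std(tr), medians = med, center = ctr, scale = scl,
              zero_var = zv, dropped = dropped)
  if (!is.null(apply)) {
    apply <- as.matrix(apply)
    a <- matrix(NA_real_, nrow(apply), length(med),
                dimnames = list(rownames(apply), names(med)))
    shared <- intersect(colnames(apply) %||% names(med), names(med))
    a[, shared] <- apply[, shared]
    out$apply <- std(fill(a))
  }
  out
}

#' Fit a PCA + LASSO logistic seizure-laterality model
#'
#' The core classifier: the binary response is 1 when the patient's
#' clinician-determined laterality equals the target side (left versus
#' right-or-bilateral, or right versus left-or-bilateral). AI features are
#' median-imputed and z-scored on the training data, projected onto the
#' smallest set of principal components explaining at least `var_explained`
#' of the training variance, and classified by L1-penalized logistic
#' regression with `lambda = 1/N` and inverse-class-frequency observation
#' weights.
#'
#' @param x patients x features AI matrix, or a [cohort_dataset()].
#' @param laterality per-patient labels (ignored when `x` is a dataset).
#' @param target `"left"` or `"right"`.
#' @param lambda L1 penalty; default `1/N`.
#' @param var_explained PCA variance fraction to retain (default 0.95).
#' @param class_weights use inverse-class-frequency weights (default TRUE).
#' @param threshold operating probability threshold stored with the model
#'   (typically from [loocv_laterality()]'s Youden point).
#' @return an object of class `laterality_model`.
#' @export
fit_laterality <- function(x, laterality = NULL,
                           target = c("left", "right"), lambda = NULL,
                           var_explained = 0.95, class_weights = TRUE,
                           threshold = 0.5) {
  target <- match.arg(target)
  if (inherits(x, "cohort_dataset")) { laterality <- x$laterality; x <- x$ai }
  x <- as.matrix(x)
  y <- as.integer(laterality == target)
  if (length(unique(y)) < 2) stop("single-class training labels")
  n <- nrow(x)
  lambda <- lambda %||% (1 / n)
  si <- standardize_impute(x)
  pc <- prcomp(si$train, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  ev <- ev / sum(ev)
  k <- which(cumsum(ev) >= var_explained - 1e-12)[1]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- si$train %*% rot
  w <- if (class_weights) {
    tab <- table(y)
    as.numeric(n / (2 * tab[as.character(y)]))
  } else rep(1, n)
  fit <- lasso_logistic(scores, y, lambda, weights = w)
  structure(list(
    target = target, medians = si$medians, center = si$center,
    scale = si$scale, zero_var = si$zero_var, dropped = si$dropped,
    rotation = rot, k = k, explained = sum(ev[seq_len(k)]),
    intercept = fit$intercept, beta = fit$beta, lambda = lambda,
    class_weights = class_weights, threshold = threshold,
    feature_names = names(si$medians), n_train = n),
    class = "laterality_model")
}

# frozen transform of new AI rows into PCA scores
model_scores <- function(object, x) {
  x <- as.matrix(x)
  if (is.null(colnames(x)) && ncol(x) == length(object$feature_names))
    colnames(x) <- object$feature_names
  a <- matrix(NA_real_, nrow(x), length(object$medians),
              dimnames = list(rownames(x), object$feature_names))
  shared <- intersect(colnames(x), object$feature_names)
  if (!length(shared)) stop("no overlapping feature keys")
  a[, shared] <- x[, shared]
  for (j in seq_len(ncol(a))) a[is.na(a[, j]), j] <- object$medians[j]
  a <- sweep(sweep(a, 2, object$center), 2, object$scale, "/")
  a[, object$zero_var] <- 0
  a %*% object$rotation
}

#' @param object a `laterality_model`.
#' @param newdata AI matrix to predict.
#' @param type `"response"` (probability) or `"link"` (logit).
#' @param ... unused.
#' @rdname fit_laterality
#' @export
predict.laterality_model <- function(object, newdata, type = c("response",
                                                               "link"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "cohort_dataset")) newdata <- newdata$ai
  eta <- drop(model_scores(object, newdata) %*% object$beta) +
    object$intercept
  if (type == "link") eta else 1 / (1 + exp(-eta))
}

#' @param x,object a `laterality_model`.
#' @rdname fit_laterality
#' @export
print.laterality_model <- function(x, ...) {
  cat(sprintf(
    "<laterality_model> %s-sided SOZ vs rest: %d features -> %d PCs (%.1f%% var), lambda = %.4g\n",
    x$target, length(x$feature_names), x$k, 100 * x$explained, x$lambda))
  cat(sprintf("  nonzero PC coefficients: %d of %d; threshold %.3f\n",
              sum(x$beta != 0), x$k, x$threshold))
  invisible(x)
}

#' @rdname fit_laterality
#' @export
coef.laterality_model <- function(object, ...) {
  feature_importance(object)
}

#' @rdname fit_laterality
#' @export
summary.laterality_model <- function(object, ...) {
  imp <- sort(abs(feature_importance(object)), decreasing = TRUE)
  print(object)
  cat("  top features by |standardized weight|:\n")
  top <- head(imp[imp > 0], 10)
  if (!length(top)) cat("    (all weights zero)\n")
  else for (i in seq_along(top))
    cat(sprintf("    %-32s %.4f\n", names(top)[i], top[i]))
  invisible(imp)
}

#' Standardized per-feature model weights
#'
#' Maps the LASSO coefficients back from principal-component space to the
#' original AI features by multiplying the PCA loading matrix with the
#' coefficient vector; the absolute values rank feature importance.
#'
#' @param model a `laterality_model`.
#' @return named numeric vector over the training features.
#' @export
feature_importance <- function(model) {
  drop(model$rotation %*% model$beta)
}

#' ROC curve and AUC
#'
#' AUC via the Mann--Whitney statistic (ties counted 1/2), with the full ROC
#' point set.
#'
#' @param labels binary 0/1 (or logical) outcome.
#' @param scores predicted probabilities or scores.
#' @return list with `auc` and `roc` (data.frame `threshold`, `sensitivity`,
#'   `specificity`).
#' @export
roc_auc <- function(labels, scores) {
  y <- as.integer(labels)
  keep <- !is.na(y) & !is.na(scores)
  y <- y[keep]; s <- scores[keep]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined with a single class")
  r <- rank(s)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(-Inf, sort(unique(s)), Inf)
  roc <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(s[y == 1] >= t), 1),
    specificity = vapply(thr, function(t) mean(s[y == 0] < t), 1))
  list(auc = auc, roc = roc)
}

#' Optimal operating point on pooled cross-validated probabilities
#'
#' Chooses the threshold maximizing Youden's J (sensitivity + specificity -
#' 1); candidate thresholds are midpoints between consecutive sorted unique
#' scores (plus the extremes), with ties broken toward the lower threshold.
#'
#' @inheritParams roc_auc
#' @return list with `threshold`, `confusion` (2x2 matrix), `sensitivity`,
#'   `specificity`, `balanced_accuracy`, `youden`.
#' @export
operating_point <- function(labels, scores) {
  y <- as.integer(labels); s <- as.numeric(scores)
  keep <- !is.na(y) & !is.na(s); y <- y[keep]; s <- s[keep]
  u <- sort(unique(s))
  cand <- if (length(u) > 1)
    c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  else c(u - 1, u + 1)
  best <- NULL
  for (t in cand) {
    sens <- mean(s[y == 1] >= t); spec <- mean(s[y == 0] < t)
    J <- sens + spec - 1
    if (is.null(best) || J > best$youden + 1e-12) {
      best <- list(threshold = t, sensitivity = sens, specificity = spec,
                   youden = J)
    }
  }
  t <- best$threshold
  conf <- matrix(c(sum(y == 1 & s >= t), sum(y == 0 & s >= t),
                   sum(y == 1 & s < t), sum(y == 0 & s < t)),
                 2, 2, byrow = TRUE,
                 dimnames = list(predicted = c("positive", "negative"),
                                 actual = c("positive", "negative")))
  best$confusion <- conf
  best$balanced_accuracy <- (best$sensitivity + best$specificity) / 2
  best
}

#' Leave-one-patient-out cross-validation of the laterality model
#'
#' For each patient, the entire pipeline (imputation, standardization, PCA,
#' LASSO) is refit on the remaining patients and the held-out probability
#' recorded; pooled probabilities give the ROC, AUC and the Youden operating
#' point. Folds whose training labels collapse to one class are skipped with
#' a warning.
#'
#' @inheritParams fit_laterality
#' @param feature_subset optional column names to restrict the model to
#'   (e.g. the sleep CAR spike-rate AI for the spike-only model).
#' @return a `laterality_cv` object: `probabilities`, `response`, `auc`,
#'   `roc`, `threshold`, `confusion`, `balanced_accuracy`.
#' @export
loocv_laterality <- function(x, laterality = NULL,
                             target = c("left", "right"), lambda = NULL,
                             var_explained = 0.95, class_weights = TRUE,
                             feature_subset = NULL) {
  target <- match.arg(target)
  if (inherits(x, "cohort_dataset")) { laterality <- x$laterality; x <- x$ai }
  x <- as.matrix(x)
  if (!is.null(feature_subset)) x <- x[, feature_subset, drop = FALSE]
  n <- nrow(x)
  if (n < 3) stop("leave-one-out needs n >= 3")
  y <- as.integer(laterality == target)
  prob <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2) {
      warning("fold ", i, " skipped: single-class training labels")
      next
    }
    m <- fit_laterality(x[-i, , drop = FALSE], laterality[-i], target,
                        lambda = lambda, var_explained = var_explained,
                        class_weights = class_weights)
    prob[i] <- predict(m, x[i, , drop = FALSE])
  }
  keep <- !is.na(prob)
  if (length(unique(y[keep])) < 2) {
    warning("pooled LOO probabilities cover a single class; ",
            "AUC and operating point undefined")
    ra <- list(auc = NA_real_, roc = NULL)
    op <- list(threshold = NA_real_, confusion = NULL,
               sensitivity = NA_real_, specificity = NA_real_,
               balanced_accuracy = NA_real_)
  } else {
    ra <- roc_auc(y[keep], prob[keep])
    op <- operating_point(y[keep], prob[keep])
  }
  structure(list(probabilities = prob, response = y, target = target,
                 auc = ra$auc, roc = ra$roc, threshold = op$threshold,
                 confusion = op$confusion,
                 sensitivity = op$sensitivity, specificity = op$specificity,
                 balanced_accuracy = op$balanced_accuracy, n = n),
            class = "laterality_cv")
}

#' @export
print.laterality_cv <- function(x, ...) {
  cat(sprintf(
    "<laterality_cv> %s-sided model, n = %d: AUC %.3f, balanced accuracy %.1f%% @ threshold %.3f\n",
    x$target, x$n, x$auc, 100 * x$balanced_accuracy, x$threshold))
  invisible(x)
}

#' @param x a `laterality_cv`.
#' @param ... passed to [graphics::plot()].
#' @rdname loocv_laterality
#' @export
plot.laterality_cv <- function(x, ...) {
  plot(1 - x$roc$specificity, x$roc$sensitivity, type = "s",
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("%s-sided SOZ model (AUC %.2f)", x$target, x$auc),
       xlim = c(0, 1), ylim = c(0, 1), ...)
  abline(0, 1, lty = 3)
  invisible(x)
}

#' Apply a frozen model to an external cohort
#'
#' The model trained on the full internal cohort is applied unchanged
#' (training medians, scaling, loadings, coefficients and the internal
#' operating threshold); reports AUC, the confusion matrix at the internal
#' threshold and balanced accuracy.
#'
#' @param model a `laterality_model` (with its `threshold` set from internal
#'   cross-validation).
#' @param x external AI matrix or [cohort_dataset()].
#' @param laterality external labels (ignored for a dataset).
#' @return list with `probabilities`, `auc`, `confusion`,
#'   `balanced_accuracy`, `sensitivity`, `specificity`.
#' @export
external_validate <- function(model, x, laterality = NULL) {
  if (inherits(x, "cohort_dataset")) { laterality <- x$laterality; x <- x$ai }
  x <- as.matrix(x)
  if (!nrow(x)) stop("empty external set")
  y <- as.integer(laterality == model$target)
  p <- predict(model, x)
  ra <- roc_auc(y, p)
  t <- model$threshold
  conf <- matrix(c(sum(y == 1 & p >= t), sum(y == 0 & p >= t),
                   sum(y == 1 & p < t), sum(y == 0 & p < t)),
                 2, 2, byrow = TRUE,
                 dimnames = list(predicted = c("positive", "negative"),
                                 actual = c("positive", "negative")))
  sens <- conf[1, 1] / sum(conf[, 1]); spec <- conf[2, 2] / sum(conf[, 2])
  list(probabilities = p, auc = ra$auc, confusion = conf,
       sensitivity = sens, specificity = spec,
       balanced_accuracy = (sens + spec) / 2)
}

#' Binarize a spike-rate asymmetry index
#'
#' Codes the qualitative clinical judgement "more spikes on the left": 1 for
#' positive AI, 0 for negative. An exactly zero AI is coded 0 with a warning
#' (documented tie rule); missing stays missing.
#'
#' @param ai numeric vector of spike-rate AIs.
#' @return integer vector of 0/1 (or `NA`).
#' @export
binarize_spike_ai <- function(ai) {
  out <- ifelse(is.na(ai), NA_integer_, ifelse(ai > 0, 1L, 0L))
  if (any(!is.na(ai) & ai == 0))
    warning("AI exactly 0 coded as 0 (tie rule)")
  out
}

#' Model AUC as a function of sampled spike-rate duration
#'
#' Emulates shortening the recording: for each duration `d`, repeatedly draw
#' `d` random one-minute sleep segments per patient (without replacement,
#' capped at the available count with a warning), recompute the spike-rate
#' AI from those minutes only, rerun leave-one-out cross-validation, and
#' average the AUC over repetitions. Requesting every available segment is a
#' degenerate draw and reproduces the full-duration AUC exactly.
#'
#' @param counts_list per-patient spike-count matrices (channels x sleep
#'   segments) as from [sleep_spike_counts()], each with a `side` attribute.
#' @param laterality per-patient labels.
#' @param minutes integer vector of sampled durations.
#' @param reps repetitions per duration.
#' @param seed integer seed.
#' @param target model side.
#' @return data.frame with `minutes`, `auc` (mean over reps), `sd`.
#' @export
duration_subsample_experiment <- function(counts_list, laterality,
                                          minutes, reps = 3, seed = 1,
                                          target = "left") {
  avail <- vapply(counts_list, ncol, 1L)
  minutes <- as.integer(minutes)
  if (any(minutes > min(avail))) {
    warning("requested duration exceeds available segments; capped")
  }
  with_seed(seed, {
    res <- lapply(minutes, function(d) {
      aucs <- vapply(seq_len(reps), function(r) {
        ai <- vapply(seq_along(counts_list), function(i) {
          cm <- counts_list[[i]]
          di <- min(d, ncol(cm))
          sel <- if (di == ncol(cm)) seq_len(ncol(cm))
                 else sort(sample.int(ncol(cm), di))
          side <- attr(cm, "side")
          rates <- rowSums(cm[, sel, drop = FALSE]) / di
          asymmetry_index(mean(rates[side == "L"]),
                          mean(rates[side == "R"]))
        }, numeric(1))
        m <- matrix(ai, ncol = 1,
                    dimnames = list(NULL, "spikes__bb__car__sleep"))
        loocv_laterality(m, laterality, target)$auc
      }, numeric(1))
      data.frame(minutes = d, auc = mean(aucs), sd = sd(aucs))
    })
    do.call(rbind, res)
  })
}

#' Spike-rate laterality calculator
#'
#' The bedside-calculator entry point: given left and right temporal spike
#' rates from N2/N3 sleep (spikes/min), returns the spike-rate AI and the
#' predicted probabilities of left- and right-sided seizure onset from the
#' two single-feature spike models.
#'
#' @param left_rate,right_rate spike rates in spikes/min (>= 0, not both 0).
#' @param left_model,right_model fitted single-feature `laterality_model`s
#'   (feature `spikes__bb__car__sleep`).
#' @return list with `ai`, `p_left`, `p_right`.
#' @export
#' @examples \dontrun{predict_calculator(10, 2, left_m, right_m)}
predict_calculator <- function(left_rate, right_rate, left_model,
                               right_model) {
  if (left_rate < 0 || right_rate < 0) stop("rates must be >= 0")
  if (left_rate + right_rate == 0)
    stop("AI undefined: both spike rates are zero")
  ai <- asymmetry_index(left_rate, right_rate)
  m <- matrix(ai, ncol = 1, dimnames = list(NULL, "spikes__bb__car__sleep"))
  list(ai = ai,
       p_left = unname(predict(left_model, m)),
       p_right = unname(predict(right_model, m)))
}

#' Serialize a laterality model to JSON
#'
#' Stores every frozen statistic (medians, centring, loadings, coefficients,
#' threshold) so the model can be reloaded and applied elsewhere.
#'
#' @param model a `laterality_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_laterality_model <- function(model, path) {
  obj <- unclass(model)
  obj$rotation <- list(dim = dim(model$rotation),
                       values = as.numeric(model$rotation))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @param path JSON file from [write_laterality_model()].
#' @rdname write_laterality_model
#' @export
read_laterality_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$rotation <- matrix(obj$rotation$values, obj$rotation$dim[1],
                         obj$rotation$dim[2])
  for (f in c("medians", "center", "scale"))
    obj[[f]] <- setNames(as.numeric(obj[[f]]), obj$feature_names)
  obj$zero_var <- as.logical(obj$zero_var)
  obj$beta <- as.numeric(obj$beta)
  structure(obj, class = "laterality_model")
}
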