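#' Asymmetry index
#'
#' \eqn{AI = (L - R)/(L + R)} for a hemisphere-averaged, non-negative
#' feature. Positive means the feature is larger on the left. Missing when
#' either side is missing or the denominator is degenerate
#' (`|L + R| < eps`).
#'
#' @param feature_left,feature_right side-aggregated feature values (>= 0).
#' @param eps degenerate-denominator guard.
#' @return AI in `[-1, 1]`, or `NA`.
#' @export
#' @examples
#' asymmetry_index(3, 1)  # 0.5
asymmetry_index <- function(feature_left, feature_right, eps = 1e-12) {
  if (length(feature_left) != 1 || length(feature_right) != 1)
    stop("asymmetry_index takes scalar side aggregates")
  if (is.na(feature_left) || is.na(feature_right)) return(NA_real_)
  if (feature_left < 0 || feature_right < 0)
    stop("asymmetry index requires non-negative feature values")
  s <- feature_left + feature_right
  if (abs(s) < eps) return(NA_real_)
  (feature_left - feature_right) / s
}

#' Aggregate a grid cell into left and right side values
#'
#' Univariate cells (per-channel vectors) are averaged over the retained
#' contacts of each hemisphere; bivariate cells (channel x channel matrices)
#' are averaged over intra-hemispheric pairs only (cross-hemisphere entries
#' are excluded). Missing entries are dropped from the means; a side with no
#' non-missing value is missing.
#'
#' @param cell named numeric vector or symmetric matrix from a
#'   [compute_feature_grid()] cell.
#' @param side named character vector mapping each channel to `"L"`/`"R"`.
#' @return `c(left = , right = )`.
#' @export
aggregate_feature_sides <- function(cell, side) {
  side <- side[if (is.matrix(cell)) rownames(cell) else names(cell)]
  one <- function(s) {
    if (is.matrix(cell)) {
      ix <- which(side == s)
      if (length(ix) < 2) return(NA_real_)
      vals <- cell[ix, ix][upper.tri(matrix(0, length(ix), length(ix)))]
    } else vals <- cell[side == s]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) NA_real_ else mean(vals)
  }
  c(left = one("L"), right = one("R"))
}

#' Asymmetry-index vector from a feature grid
#'
#' Collapses every grid cell into one AI value, keyed canonically.
#'
#' @param grid a `feature_grid`.
#' @return named numeric vector over `grid$keys` (possibly `NA`), with an
#'   attribute `n_side` giving retained contact counts per reference.
#' @export
ai_from_grid <- function(grid) {
  out <- setNames(rep(NA_real_, length(grid$keys)), grid$keys)
  for (key in grid$keys) {
    cell <- grid$cells[[key]]
    if (is.null(cell)) next
    ref <- strsplit(key, "__", fixed = TRUE)[[1]][3]
    sides <- aggregate_feature_sides(cell, grid$side[[ref]])
    out[key] <- asymmetry_index(sides["left"], sides["right"])
  }
  attr(out, "n_side") <- lapply(grid$side, table)
  out
}

#' Stack per-patient AI vectors into a cohort matrix
#'
#' @param ai_list list of named AI vectors (identical key sets).
#' @param keys canonical column order; defaults to the union in
#'   [ai_feature_keys()] order.
#' @return list with `ai` (patients x features matrix), `missing_fraction`
#'   per column.
#' @export
build_ai_matrix <- function(ai_list, keys = NULL) {
  if (!length(ai_list)) stop("need at least one patient")
  keys <- keys %||% names(ai_list[[1]])
  if (!length(keys)) stop("no feature keys")
  m <- t(vapply(ai_list, function(v) as.numeric(v[keys]),
                numeric(length(keys))))
  colnames(m) <- keys
  rownames(m) <- names(ai_list) %||% paste0("pt", seq_along(ai_list))
  list(ai = m, missing_fraction = colMeans(is.na(m)))
}

#' fMRI temporal-lobe connectivity asymmetry index
#'
#' Functional connectivity is the absolute Pearson correlation between
#' parcel-averaged BOLD series; each side's connectivity is the mean over its
#' intra-side parcel pairs, and the AI follows the same
#' \eqn{(L - R)/(L + R)} form as the EEG features.
#'
#' @param parcel_series timepoints x parcels numeric matrix.
#' @param left_parcels,right_parcels column indices (>= 2 each).
#' @return AI scalar, or `NA` when degenerate (constant series).
#' @export
fmri_connectivity_ai <- function(parcel_series, left_parcels, right_parcels) {
  if (length(left_parcels) < 2 || length(right_parcels) < 2)
    stop("need at least 2 parcels per side")
  if (nrow(parcel_series) < 10) stop("need at least 10 timepoints")
  sds <- apply(parcel_series, 2, sd)
  if (any(sds[c(left_parcels, right_parcels)] == 0)) return(NA_real_)
  conn <- function(ix) {
    C <- abs(cor(parcel_series[, ix]))
    mean(C[upper.tri(C)])
  }
  asymmetry_index(conn(left_parcels), conn(right_parcels))
}
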