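#' Per-feature sample variances
#'
#' Column-wise sample variance (denominator N-1) of an omics matrix, in
#' feature order. For a binary mutation column this is `n/(n-1) * p(1-p)`.
#'
#' @param m an `omics_matrix` or numeric matrix.
#' @return Named numeric vector of variances.
#' @export
feature_variances <- function(m) {
  x <- as_values(m)
  n <- nrow(x)
  if (n < 2) stop("at least 2 samples are required to estimate variances")
  centred <- sweep(x, 2, colMeans(x))
  v <- colSums(centred^2) / (n - 1)
  names(v) <- colnames(x)
  v
}

#' Elbow (knee) threshold on a variance profile
#'
#' Sorts variances in decreasing order, min-max scales index and variance to
#' the unit square (so the rule is unit-invariant), and locates the knee of
#' the scree curve: the point with the largest perpendicular distance to the
#' chord joining the first and last points, ties to the smaller index (more
#' conservative: fewer features kept). The knee point is the first feature
#' on the low-variance side of the bend, so the returned threshold is the
#' variance of the point immediately before it — the last feature kept.
#'
#' @param variances numeric vector of feature variances.
#' @return The threshold variance.
#' @examples
#' elbow_threshold(c(10, 9.5, 9, 0.5, 0.4, 0.3, 0.2)) # 9
#' elbow_threshold(c(100, 100, 1, 1, 1))              # 100
#' @export
elbow_threshold <- function(variances) {
  v <- sort(as.numeric(variances), decreasing = TRUE)
  n <- length(v)
  if (n < 3) stop("at least 3 variances are required")
  rng <- v[1] - v[n]
  if (rng == 0) stop("degenerate variance curve: all variances are equal")
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (v - v[n]) / rng
  # chord runs from (0, 1) to (1, 0); perpendicular distance is
  # |x + y - 1| / sqrt(2)
  d <- abs(x + y - 1)
  k <- which.max(d)
  if (d[k] <= 1e-12) {
    stop("degenerate variance curve: collinear scree")
  }
  v[k - 1]
}

#' Fit a high-variance feature mask
#'
#' Stage 1 of the pipeline: computes training-set feature variances, picks a
#' threshold by [elbow_threshold()], and retains features with variance at or
#' above it (order-preserving). If the variance curve is degenerate the mask
#' keeps all features and records the minimum variance as threshold.
#' `top_k` overrides the elbow rule with a fixed feature count.
#'
#' Masks must be fit on training samples only; applying a mask never consults
#' the target matrix's values.
#'
#' @param m an `omics_matrix` (training samples).
#' @param top_k optional fixed number of features to keep (largest variances,
#'   ties broken by original column order).
#' @return An object of class `feature_mask`: `kind`, `features`,
#'   `threshold`, `variances`.
#' @export
fit_mask <- function(m, top_k = NULL) {
  stopifnot(inherits(m, "omics_matrix"))
  v <- feature_variances(m)
  if (!is.null(top_k)) {
    top_k <- as.integer(top_k)
    if (top_k < 1 || top_k > length(v)) stop("top_k out of range")
    keep <- sort(order(-v)[seq_len(top_k)])
    thr <- min(v[keep])
  } else {
    thr <- tryCatch(elbow_threshold(v), error = function(e) NA_real_)
    if (is.na(thr)) thr <- min(v)   # degenerate fallback: keep everything
    keep <- which(v >= thr)
  }
  structure(list(kind = m$kind, features = m$feature_ids[keep],
                 threshold = thr, variances = v),
            class = "feature_mask")
}

#' @export
print.feature_mask <- function(x, ...) {
  cat(sprintf("feature_mask [%s]: %d / %d features, variance >= %.4g\n",
              x$kind, length(x$features), length(x$variances), x$threshold))
  invisible(x)
}

#' Apply a feature mask
#'
#' Subsets an omics matrix to the mask's features, in mask order.
#'
#' @param m an `omics_matrix`; must contain every mask feature.
#' @param mask a `feature_mask`.
#' @return The reduced `omics_matrix`.
#' @export
apply_mask <- function(m, mask) {
  stopifnot(inherits(m, "omics_matrix"), inherits(mask, "feature_mask"))
  missing <- setdiff(mask$features, m$feature_ids)
  if (length(missing) > 0) {
    stop(sprintf("mask mismatch: %d mask features absent from matrix (e.g. %s)",
                 length(missing), missing[1]))
  }
  omics_subset(m, features = mask$features)
}

# JSON-serialisable representation of a mask (for run artifacts)
mask_to_list <- function(mask) {
  list(kind = mask$kind, threshold = mask$threshold,
       features = as.list(mask$features))
}
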