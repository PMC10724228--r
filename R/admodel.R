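#' @name admodel
#' @title k-nearest-neighbor applicability domain
#'
#' @description
#' A query polymer should only be scored when its fingerprint lies near the
#' training data. The applicability domain is defined by the mean Euclidean
#' distance to the k nearest training fingerprints: the cutoff is a
#' percentile (default 95) of the same statistic evaluated over the training
#' set itself, leave-self-out.
NULL

# Euclidean distances from each row of A to each row of B (n_A x n_B).
cross_dist <- function(A, B) {
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

mean_knn_dist <- function(D, k) {
  apply(D, 1, function(row) mean(sort(row)[seq_len(k)]))
}

#' Fit the applicability-domain model
#'
#' @param reference_fingerprints matrix of training fingerprints.
#' @param k neighbor count (default 5); must satisfy 1 <= k < n.
#' @param percentile percentile (0-100) of the leave-self-out mean kNN
#'   distances used as the in-domain cutoff (default 95).
#' @return object of class `ad_model`: reference matrix, `k`, `threshold`,
#'   `percentile`, `distance = "euclidean"`, `scheme_id`, and the per-point
#'   leave-self-out distances `reference_distances`.
#' @export
fit_ad <- function(reference_fingerprints, k = 5L, percentile = 95) {
  X <- as.matrix(reference_fingerprints)
  n <- nrow(X)
  if (k < 1 || k >= n) {
    stop("need 1 <= k < number of reference points (n = ", n, ")",
         call. = FALSE)
  }
  D <- cross_dist(X, X)
  diag(D) <- Inf  # leave-self-out
  ref_d <- mean_knn_dist(D, k)
  threshold <- as.numeric(stats::quantile(ref_d, percentile / 100, type = 7))
  structure(list(reference = X, k = as.integer(k), threshold = threshold,
                 percentile = percentile, distance = "euclidean",
                 scheme_id = attr(reference_fingerprints, "scheme_id"),
                 reference_distances = ref_d),
            class = "ad_model")
}

#' @export
print.ad_model <- function(x, ...) {
  cat(sprintf(
    "ad_model: %d reference points, k = %d, threshold = %.4g (%gth pct, %s)\n",
    nrow(x$reference), x$k, x$threshold, x$percentile, x$distance))
  invisible(x)
}

#' Applicability-domain membership of query fingerprints
#'
#' @param ad an `ad_model` from [fit_ad()].
#' @param x query fingerprint vector or matrix under the reference scheme.
#' @return data.frame with columns `in_domain` (logical) and `distance`
#'   (mean distance to the k nearest reference points).
#' @export
in_domain <- function(ad, x) {
  stopifnot(inherits(ad, "ad_model"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  sx <- attr(x, "scheme_id")
  if (!is.null(sx) && !is.null(ad$scheme_id) && !identical(sx, ad$scheme_id)) {
    stop("query scheme '", sx, "' does not match reference scheme '",
         ad$scheme_id, "'", call. = FALSE)
  }
  D <- cross_dist(x, ad$reference)
  d <- mean_knn_dist(D, ad$k)
  data.frame(in_domain = d <= ad$threshold, distance = d)
}
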