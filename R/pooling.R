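#' Top-k average pooling
#'
#' Reduces a feature pool to a scalar: sort descending and average the k
#' largest values with uniform weight 1/k. `k = 1` is maximum pooling,
#' `k = length(values)` is average pooling.
#'
#' @param values Finite numeric vector (the pool).
#' @param k Pool depth, `1 <= k <= length(values)`.
#' @return The mean of the k largest values.
#' @examples
#' pool_topk(c(5, 1, 3), 1) # 5
#' pool_topk(c(5, 1, 3), 2) # 4
#' pool_topk(c(5, 1, 3), 3) # 3
#' @export
pool_topk <- function(values, k) {
  if (!length(values)) stop("empty pool")
  if (!all(is.finite(values))) stop("pool contains non-finite values")
  if (length(k) != 1L || !is.finite(k) || k < 1 || k > length(values) ||
      k != round(k))
    stop("k must be an integer in [1, ", length(values), "]")
  mean(sort(values, decreasing = TRUE)[seq_len(k)])
}

# all top-k means of one pool in O(n log n): sorted cumulative means
topk_curve <- function(values) {
  cumsum(sort(values, decreasing = TRUE)) / seq_along(values)
}

#' Histogram information entropy of a pooled feature across subjects
#'
#' Shannon entropy (natural log) of the equal-width `n_bins` histogram
#' spanning `[min, max]` of the values: `H = -sum p log p` over non-empty
#' bins. Constant input has zero entropy ("all of the sample is the
#' same"); the maximum, `log(n_bins)`, is attained when the bins are
#' uniformly filled.
#'
#' @param values Finite numeric vector, one pooled value per subject
#'   (length >= 2).
#' @param n_bins Number of bins (default 10, >= 2).
#' @return Entropy in nats.
#' @export
feature_entropy <- function(values, n_bins = 10L) {
  if (length(values) < 2L) stop("need at least 2 subjects")
  if (!all(is.finite(values))) stop("values must be finite")
  if (n_bins < 2L) stop("n_bins must be >= 2")
  rng <- range(values)
  if (rng[1] == rng[2]) return(0)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  cnt <- tabulate(findInterval(values, edges, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = n_bins)
  p <- cnt / sum(cnt)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Select the pool depth k that maximises cohort information entropy
#'
#' For one feature: every subject's pool is reduced by [pool_topk()] at
#' each candidate depth `k = 1 ... min(pool lengths)` and the
#' cross-subject [feature_entropy()] of the pooled values computed; the
#' smallest k attaining the maximal entropy is selected (ties broken
#' towards small k for reproducibility).
#'
#' @param pools List of numeric vectors, one pool per subject.
#' @param n_bins Histogram bins for the entropy estimate.
#' @param feature_name Optional label carried into the result.
#' @return Object of class `k_selection`: list with `feature_name`, `k`,
#'   `entropy` (at the selected k) and `entropy_curve` (all candidates).
#' @export
select_k <- function(pools, n_bins = 10L, feature_name = NA_character_) {
  if (length(pools) < 2L) stop("need a cohort of at least 2 subjects")
  lens <- lengths(pools)
  if (any(lens < 1L)) stop("every subject needs a non-empty pool")
  kmax <- min(lens)
  curves <- vapply(pools, function(p) topk_curve(p)[seq_len(kmax)],
                   numeric(kmax))
  if (kmax == 1L) curves <- matrix(curves, nrow = 1L)
  h <- apply(curves, 1L, feature_entropy, n_bins = n_bins)
  k <- which.max(h) # which.max returns the first (smallest) maximiser
  structure(
    list(feature_name = feature_name, k = as.integer(k),
         entropy = h[k], entropy_curve = as.numeric(h)),
    class = "k_selection"
  )
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("<k_selection> %s: k = %d, H = %.4f (curve over %d candidates)\n",
              ifelse(is.na(x$feature_name), "feature", x$feature_name),
              x$k, x$entropy, length(x$entropy_curve)))
  invisible(x)
}

#' Entropy-based k selection for all 18 features
#'
#' @param pyramids List of `hrv_pyramid` objects (one per subject).
#' @param n_bins Histogram bins.
#' @return Named list of [select_k()] results, one per feature.
#' @export
select_k_all <- function(pyramids, n_bins = 10L) {
  stopifnot(all(vapply(pyramids, inherits, logical(1), "hrv_pyramid")))
  out <- lapply(hrv_feature_names, function(nm) {
    select_k(lapply(pyramids, function(p) p$pools[[nm]]),
             n_bins = n_bins, feature_name = nm)
  })
  names(out) <- hrv_feature_names
  out
}

#' Pool a cohort of pyramids into one row of 18 scalars per subject
#'
#' @param pyramids List of `hrv_pyramid` objects.
#' @param k_by_feature Named integer vector or list with one k per
#'   feature ([hrv_feature_names]); also accepts the output of
#'   [select_k_all()]. A k exceeding a subject's realised pool length is
#'   clamped to that length (average pooling of what is there).
#' @param labels Optional vector of severity labels (one per subject).
#' @return data.frame with `subject_id`, `label` and the 18 pooled
#'   feature columns.
#' @export
pool_cohort <- function(pyramids, k_by_feature, labels = NULL) {
  stopifnot(all(vapply(pyramids, inherits, logical(1), "hrv_pyramid")))
  if (is.list(k_by_feature) &&
      all(vapply(k_by_feature, inherits, logical(1), "k_selection")))
    k_by_feature <- vapply(k_by_feature, function(s) s$k, integer(1))
  missing_k <- setdiff(hrv_feature_names, names(k_by_feature))
  if (length(missing_k))
    stop("k_by_feature lacks entries for: ", paste(missing_k, collapse = ", "))
  rows <- lapply(seq_along(pyramids), function(i) {
    p <- pyramids[[i]]
    if (is.null(p$pools)) stop("subject ", i, " has no pyramid")
    vals <- vapply(hrv_feature_names, function(nm) {
      pool <- p$pools[[nm]]
      pool_topk(pool, min(as.integer(k_by_feature[[nm]]), length(pool)))
    }, numeric(1))
    data.frame(subject_id = p$subject_id,
               label = if (is.null(labels)) NA_character_
                       else as.character(labels[i]),
               as.list(vals))
  })
  do.call(rbind, rows)
}
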