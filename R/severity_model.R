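#' Assign a hypertension severity tag from blood pressure
#'
#' ESH-style grading: SBP and DBP are classified independently against the
#' guideline rows (normal < 120/< 80; high-normal 120–139 / 80–89; grade I
#' 140–159 / 90–99; grade II 160–180 / 100–109; grade III >= 180 / >= 110)
#' and the final class is the more severe of the two. Normal maps to
#' `mild`, high-normal and grade I to `moderate`, grades II and III to
#' `severe`.
#'
#' @param sbp Systolic pressure, mmHg (> 0).
#' @param dbp Diastolic pressure, mmHg (> 0, < sbp).
#' @return One of `"mild"`, `"moderate"`, `"severe"`. Vectorised.
#' @examples
#' assign_severity(118, 75)  # mild
#' assign_severity(150, 95)  # moderate
#' assign_severity(185, 115) # severe
#' @export
assign_severity <- function(sbp, dbp) {
  if (length(sbp) != length(dbp)) stop("sbp and dbp must have equal length")
  if (any(!is.finite(sbp)) || any(!is.finite(dbp)) ||
      any(sbp <= 0) || any(dbp <= 0))
    stop("blood pressures must be positive finite mmHg values")
  if (any(sbp <= dbp))
    stop("systolic pressure must exceed diastolic pressure")
  sev_s <- ifelse(sbp < 120, 1L, ifelse(sbp < 160, 2L, 3L))
  sev_d <- ifelse(dbp < 80, 1L, ifelse(dbp < 100, 2L, 3L))
  severity_levels[pmax(sev_s, sev_d)]
}

#' One-way ANOVA F statistic of a feature across classes
#'
#' Textbook decomposition: `F = MSB / MSW` with
#' `MSB = sum_g n_g (xbar_g - xbar)^2 / (g - 1)` and
#' `MSW = sum_g sum_i (x_gi - xbar_g)^2 / (N - g)`. For the three severity
#' classes `df_between = 2`.
#'
#' @param values Finite numeric vector.
#' @param labels Class labels (factor or character), same length; at
#'   least 2 classes with at least 2 members each.
#' @return List with `F`, `df_between`, `df_within`. Zero within-group
#'   variance with unequal means yields `F = Inf` with a warning; equal
#'   group means yield `F = 0`.
#' @export
anova_f <- function(values, labels) {
  if (length(values) != length(labels)) stop("values/labels length mismatch")
  if (!all(is.finite(values))) stop("values must be finite")
  labels <- factor(labels)
  g <- nlevels(labels)
  if (g < 2L) stop("need at least 2 classes")
  cnt <- table(labels)
  if (any(cnt < 2L)) stop("every class needs at least 2 members")
  n <- length(values)
  gm <- mean(values)
  means <- tapply(values, labels, mean)
  ssb <- sum(cnt * (means - gm)^2)
  ssw <- sum((values - means[labels])^2)
  dfb <- g - 1L
  dfw <- n - g
  if (ssb == 0) {
    f <- 0
  } else if (ssw == 0) {
    warning("zero within-group variance with unequal means: F is infinite")
    f <- Inf
  } else {
    f <- (ssb / dfb) / (ssw / dfw)
  }
  list(F = f, df_between = dfb, df_within = dfw)
}

#' Per-feature ANOVA F-measure selection
#'
#' Computes [anova_f()] for every feature column and selects those with a
#' strictly greater F than `threshold` (default 1).
#'
#' @param x data.frame or matrix of features (columns) by subjects
#'   (rows); typically the pooled table of [pool_cohort()].
#' @param labels Severity labels, one per row.
#' @param threshold Selection threshold on F (strict inequality).
#' @return Object of class `selection_report`: list with `table`
#'   (data.frame: feature, F, df_between, df_within, selected),
#'   `threshold`, `selected` (character vector of feature names).
#' @export
select_features <- function(x, labels, threshold = 1.0) {
  if (is.data.frame(x)) {
    feat_cols <- intersect(hrv_feature_names, names(x))
    if (!length(feat_cols)) feat_cols <- names(x)[vapply(x, is.numeric, logical(1))]
    x <- as.matrix(x[, feat_cols, drop = FALSE])
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  res <- lapply(seq_len(ncol(x)), function(j) anova_f(x[, j], labels))
  tab <- data.frame(
    feature = colnames(x),
    F = vapply(res, `[[`, numeric(1), "F"),
    df_between = vapply(res, `[[`, integer(1), "df_between"),
    df_within = vapply(res, `[[`, integer(1), "df_within")
  )
  tab$selected <- tab$F > threshold
  structure(
    list(table = tab, threshold = threshold,
         selected = tab$feature[tab$selected]),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> %d/%d features with F > %g:\n",
              length(x$selected), nrow(x$table), x$threshold))
  tab <- x$table[order(-x$table$F), ]
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-7s F = %8.3f (df %d, %d)%s\n", tab$feature[i], tab$F[i],
                tab$df_between[i], tab$df_within[i],
                ifelse(tab$selected[i], "  *", "")))
  invisible(x)
}

# fit + predict one classifier; features standardised with training
# statistics. Seeded immediately before each stochastic fit.
fit_predict <- function(train_x, train_y, test_x, classifier, seed) {
  mu <- colMeans(train_x)
  sg <- apply(train_x, 2L, stats::sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  tr <- scale(train_x, center = mu, scale = sg)
  te <- scale(test_x, center = mu, scale = sg)
  train_y <- factor(train_y)
  set.seed(seed)
  pred <- switch(classifier,
    nb = {
      fit <- e1071::naiveBayes(tr, train_y)
      stats::predict(fit, te)
    },
    svm = {
      fit <- e1071::svm(tr, train_y, kernel = "radial")
      stats::predict(fit, te)
    },
    bpnn = {
      fit <- nnet::nnet(tr, nnet::class.ind(train_y), size = 16L,
                        decay = 5e-4, maxit = 300L, trace = FALSE,
                        softmax = TRUE, MaxNWts = 5000L)
      p <- stats::predict(fit, te)
      factor(levels(train_y)[max.col(p)], levels = levels(train_y))
    },
    rf = {
      fit <- randomForest::randomForest(tr, train_y, ntree = 100L)
      stats::predict(fit, te)
    },
    stop("unknown classifier: ", classifier,
         " (use one of nb, svm, bpnn, rf)")
  )
  factor(as.character(pred), levels = levels(train_y))
}

#' Stratified cross-validated severity classification
#'
#' Evaluates a classifier under stratified k-fold cross-validation. When
#' `x` is a list of `hrv_pyramid` objects, the entropy-based pool-depth
#' selection ([select_k_all()]) and the ANOVA F > threshold feature
#' selection are re-fitted inside every training fold (no leakage into the
#' held-out subjects); pass a plain numeric matrix to skip pooling and
#' control feature selection with `select`.
#'
#' Per-class precision and recall come from the confusion matrix pooled
#' over the out-of-fold predictions: `precision = TP / (TP + FP) * 100`,
#' `recall = TP / (TP + FN) * 100`; overall precision is the micro-average
#' (pooled `sum(TP) / N * 100`).
#'
#' @param x List of `hrv_pyramid` objects or numeric matrix (subjects in
#'   rows).
#' @param y Severity labels, one per subject.
#' @param classifier `"rf"`, `"nb"`, `"svm"` or `"bpnn"`.
#' @param folds Number of folds (default 10); reduced with a warning when
#'   the smallest class has fewer members.
#' @param seed Integer seed controlling fold assignment and stochastic
#'   classifiers; results are bit-reproducible given (x, y, seed,
#'   classifier).
#' @param select Apply the F > `select_threshold` feature filter inside
#'   folds (default `TRUE`).
#' @param select_threshold ANOVA F selection threshold (default 1).
#' @param n_bins Histogram bins for in-fold k selection.
#' @return Object of class `hrv_cv`: list with `confusion` (classes x
#'   classes, predictions in rows), `precision`, `recall` (named per-class
#'   vectors, percent), `overall_precision` (percent, micro-average),
#'   `folds`, `seed`, `classifier`, `fold_selected` (features kept per
#'   fold), `fold_k` (per-fold selected k, when pooling in-fold).
#' @export
cross_validate <- function(x, y, classifier = c("rf", "nb", "svm", "bpnn"),
                           folds = 10L, seed = 1L, select = TRUE,
                           select_threshold = 1.0, n_bins = 10L) {
  classifier <- match.arg(classifier)
  y <- factor(y)
  pyramids <- is.list(x) && !is.data.frame(x) &&
    all(vapply(x, inherits, logical(1), "hrv_pyramid"))
  n <- if (pyramids) length(x) else nrow(x)
  if (length(y) != n) stop("y must have one label per subject")
  min_class <- min(table(y))
  if (min_class < 2L) stop("every class needs at least 2 subjects")
  if (min_class < folds) {
    warning("smallest class has ", min_class, " members; reducing folds from ",
            folds, " to ", min_class)
    folds <- min_class
  }
  set.seed(seed)
  fold_id <- integer(n)
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  classes <- levels(y)
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(predicted = classes, truth = classes))
  fold_selected <- vector("list", folds)
  fold_k <- vector("list", folds)
  for (f in seq_len(folds)) {
    test <- which(fold_id == f)
    train <- which(fold_id != f)
    if (pyramids) {
      ksel <- select_k_all(x[train], n_bins = n_bins)
      fold_k[[f]] <- vapply(ksel, function(s) s$k, integer(1))
      pooled_tr <- pool_cohort(x[train], ksel)
      pooled_te <- pool_cohort(x[test], ksel)
      xtr <- as.matrix(pooled_tr[, hrv_feature_names, drop = FALSE])
      xte <- as.matrix(pooled_te[, hrv_feature_names, drop = FALSE])
    } else {
      xtr <- as.matrix(x[train, , drop = FALSE])
      xte <- as.matrix(x[test, , drop = FALSE])
    }
    if (select) {
      rep_f <- select_features(xtr, y[train], threshold = select_threshold)
      keep <- rep_f$selected
      if (!length(keep)) { # degenerate fold: keep everything rather than nothing
        keep <- colnames(xtr)
        warning("fold ", f, ": no feature exceeded F > ", select_threshold,
                "; keeping all features")
      }
      fold_selected[[f]] <- keep
      xtr <- xtr[, keep, drop = FALSE]
      xte <- xte[, keep, drop = FALSE]
    }
    pred <- fit_predict(xtr, y[train], xte, classifier,
                        seed = seed + 1000L * f)
    tab <- table(factor(pred, levels = classes),
                 factor(y[test], levels = classes))
    confusion <- confusion + tab
  }
  metrics <- confusion_metrics(confusion)
  structure(
    c(list(confusion = confusion, folds = folds, seed = seed,
           classifier = classifier, fold_selected = fold_selected,
           fold_k = if (pyramids) fold_k else NULL),
      metrics),
    class = "hrv_cv"
  )
}

#' Precision and recall from a confusion matrix
#'
#' `precision = TP / (TP + FP) * 100`, `recall = TP / (TP + FN) * 100` per
#' class; overall precision is the micro-average `sum(TP) / N * 100`.
#'
#' @param confusion Square matrix, predictions in rows, truth in columns.
#' @return List with `precision`, `recall` (named per-class, percent) and
#'   `overall_precision`.
#' @examples
#' cm <- matrix(c(9, 1, 1, 9), 2, 2,
#'              dimnames = list(c("a", "b"), c("a", "b")))
#' confusion_metrics(cm)$precision # a: 90, b: 90
#' @export
confusion_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stop("confusion matrix must be square")
  tp <- diag(confusion)
  prec <- 100 * tp / pmax(rowSums(confusion), 1e-12)
  rec <- 100 * tp / pmax(colSums(confusion), 1e-12)
  prec[rowSums(confusion) == 0] <- NA_real_
  rec[colSums(confusion) == 0] <- NA_real_
  list(precision = prec, recall = rec,
       overall_precision = 100 * sum(tp) / sum(confusion))
}

#' @export
print.hrv_cv <- function(x, ...) {
  cat(sprintf("<hrv_cv> %s, %d-fold (seed %d): overall precision %.1f%%\n",
              x$classifier, x$folds, x$seed, x$overall_precision))
  for (cl in names(x$precision))
    cat(sprintf("  %-9s precision %5.1f%%  recall %5.1f%%\n",
                cl, x$precision[cl], x$recall[cl]))
  invisible(x)
}

#' PCA baseline feature transform
#'
#' Projects the (centred, scaled) feature matrix onto its top principal
#' components by explained variance — the conventional dimensionality
#' reduction the pyramid-pooling method is compared against.
#'
#' @param x Numeric matrix or data.frame of features (subjects in rows),
#'   complete (no missing values).
#' @param n_components Number of components to keep (default 9); must be
#'   between 1 and the rank of the centred matrix.
#' @return Matrix of component scores (subjects x components).
#' @export
pca_baseline <- function(x, n_components = 9L) {
  if (is.data.frame(x)) {
    fc <- intersect(hrv_feature_names, names(x))
    if (length(fc)) x <- x[, fc, drop = FALSE]
    x <- as.matrix(x)
  }
  if (any(!is.finite(x))) stop("feature matrix must be complete and finite")
  if (n_components < 1L) stop("n_components must be >= 1")
  keep <- apply(x, 2L, stats::sd) > 0
  x <- x[, keep, drop = FALSE]
  rk <- qr(scale(x, center = TRUE, scale = FALSE))$rank
  if (n_components > rk)
    stop("n_components = ", n_components, " exceeds the matrix rank (", rk, ")")
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  p$x[, seq_len(n_components), drop = FALSE]
}
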