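test_that("blood pressure maps to severity per the guideline rows", {
  expect_equal(assign_severity(118, 75), "mild")
  expect_equal(assign_severity(150, 95), "moderate")
  expect_equal(assign_severity(185, 115), "severe")
  # row boundaries and the higher-class-wins rule
  expect_equal(assign_severity(120, 70), "moderate") # SBP high-normal
  expect_equal(assign_severity(110, 85), "moderate") # DBP drives the class
  expect_equal(assign_severity(160, 80), "severe")
  expect_equal(assign_severity(130, 105), "severe")
  expect_error(assign_severity(80, 90), "exceed")
  expect_error(assign_severity(-120, -130), "positive")
})

test_that("anova_f reproduces textbook one-way ANOVA", {
  eq <- anova_f(rep(c(1, 2), 3), rep(c("a", "b", "c"), each = 2))
  expect_equal(eq$F, 0)
  expect_equal(eq$df_between, 2L)
  expect_equal(eq$df_within, 3L)

  # groups {0,1}, {10,11}, {20,21}: SSB = 400 (df 2), SSW = 1.5 (df 3)
  # -> F = 200 / 0.5 = 400; cross-checked against stats::oneway.test
  v <- c(0, 1, 10, 11, 20, 21)
  g <- rep(c("a", "b", "c"), each = 2)
  got <- anova_f(v, g)
  expect_equal(got$F, 400)
  ref <- oneway.test(v ~ factor(g), var.equal = TRUE)
  expect_equal(got$F, unname(ref$statistic), tolerance = 1e-12)
})

test_that("anova_f agrees with stats::oneway.test on random instances", {
  set.seed(77)
  for (i in 1:300) {
    sizes <- sample(2:8, 3, replace = TRUE)
    g <- rep(c("a", "b", "c"), sizes)
    v <- rnorm(sum(sizes), mean = sample(0:3, 1) * (g == "b"))
    got <- anova_f(v, g)
    ref <- oneway.test(v ~ factor(g), var.equal = TRUE)
    expect_equal(got$F, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$df_between, 2L)
    expect_equal(got$df_within, sum(sizes) - 3L)
  }
})

test_that("degenerate within-group variance yields the infinity sentinel", {
  expect_warning(r <- anova_f(c(1, 1, 2, 2), c("a", "a", "b", "b")),
                 "infinite")
  expect_equal(r$F, Inf)
  expect_error(anova_f(c(1, 2, 3), c("a", "a", "b")), "at least 2 members")
})

test_that("feature selection keeps strictly F > threshold", {
  g <- rep(c("a", "b", "c"), each = 4)
  x <- cbind(
    signal = rep(c(0, 5, 10), each = 4) + rep(c(-.1, .1), 6),
    flat   = rep(c(-1, 1), 6) # identical distribution in every class
  )
  rep1 <- select_features(x, g)
  expect_equal(rep1$selected, "signal")
  expect_equal(rep1$table$df_between, c(2L, 2L))
  expect_false(rep1$table$selected[rep1$table$feature == "flat"])
  # threshold is strict: a feature at exactly F = threshold is dropped
  f_signal <- rep1$table$F[rep1$table$feature == "signal"]
  rep2 <- select_features(x, g, threshold = f_signal)
  expect_length(rep2$selected, 0)
})

test_that("selection recovers exactly the informative synthetic features", {
  set.seed(5)
  n <- 20
  g <- rep(c("mild", "moderate", "severe"), each = n)
  shift <- as.integer(factor(g))
  x <- cbind(
    s1 = shift * 3 + rnorm(3 * n),
    s2 = -shift * 2 + rnorm(3 * n),
    s3 = shift + rnorm(3 * n, sd = 0.5),
    n1 = rnorm(3 * n), n2 = rnorm(3 * n), n3 = rnorm(3 * n)
  )
  rep <- select_features(x, g)
  # the informative features must pass; the exact selected set must agree
  # with an independent recomputation of every F (noise columns can land
  # on either side of the weak F > 1 bar)
  expect_true(all(c("s1", "s2", "s3") %in% rep$selected))
  f_oracle <- vapply(colnames(x), function(j)
    unname(oneway.test(x[, j] ~ factor(g), var.equal = TRUE)$statistic),
    numeric(1))
  expect_setequal(rep$selected, names(which(f_oracle > 1)))
  for (j in colnames(x)) {
    ref <- oneway.test(x[, j] ~ factor(g), var.equal = TRUE)
    expect_equal(rep$table$F[rep$table$feature == j],
                 unname(ref$statistic), tolerance = 1e-9)
  }
})

test_that("precision and recall follow the confusion-matrix arithmetic", {
  cm <- matrix(c(9, 1, 0,
                 1, 8, 1,
                 0, 1, 9), 3, 3, byrow = TRUE,
               dimnames = list(c("mild", "moderate", "severe"),
                               c("mild", "moderate", "severe")))
  m <- confusion_metrics(cm)
  expect_equal(unname(m$precision["mild"]), 90)
  expect_equal(unname(m$recall["mild"]), 90)
  expect_equal(m$overall_precision, 100 * 26 / 30)
})

test_that("cross_validate is bit-reproducible and near-perfect when separable", {
  set.seed(8)
  n <- 15
  y <- rep(c("mild", "moderate", "severe"), each = n)
  x <- cbind(f1 = rep(c(0, 10, 20), each = n) + rnorm(3 * n, sd = 0.3),
             f2 = rnorm(3 * n))
  a <- cross_validate(x, y, "rf", folds = 5, seed = 3, select = FALSE)
  b <- cross_validate(x, y, "rf", folds = 5, seed = 3, select = FALSE)
  expect_identical(a$confusion, b$confusion)
  expect_equal(a$overall_precision, 100)
  expect_true(all(a$precision == 100))
})

test_that("every classifier backend runs and beats chance when separable", {
  set.seed(9)
  n <- 12
  y <- rep(c("mild", "moderate", "severe"), each = n)
  x <- cbind(f1 = rep(c(0, 6, 12), each = n) + rnorm(3 * n, sd = 0.5),
             f2 = rep(c(5, 0, -5), each = n) + rnorm(3 * n, sd = 0.5))
  for (clf in c("nb", "svm", "bpnn", "rf")) {
    m <- cross_validate(x, y, clf, folds = 4, seed = 2, select = FALSE)
    expect_gte(m$overall_precision, 80)
  }
})

test_that("folds are reduced with a warning for small classes", {
  y <- rep(c("a", "b", "c"), each = 3)
  x <- matrix(rnorm(18), 9, 2)
  expect_warning(m <- cross_validate(x, y, "rf", folds = 10, seed = 1,
                                     select = FALSE),
                 "reducing folds")
  expect_equal(m$folds, 3L)
})

test_that("in-fold selection pipeline runs on pyramid input", {
  co <- small_pyramid_cohort()
  m <- cross_validate(co$pyramids, co$labels, "rf", folds = 3, seed = 4)
  expect_s3_class(m, "hrv_cv")
  expect_equal(sum(m$confusion), length(co$labels))
  expect_length(m$fold_k, 3)
  expect_named(m$fold_k[[1]], hrv_feature_names)
  # the synthetic classes are strongly separated
  expect_gte(m$overall_precision, 80)
})

test_that("PCA baseline matches an eigendecomposition oracle", {
  set.seed(10)
  n <- 40
  block1 <- matrix(rnorm(n), n, 1) %*% c(1, 1, 0, 0)
  block2 <- matrix(rnorm(n), n, 1) %*% c(0, 0, 1, -1)
  x <- block1 * 3 + block2 + matrix(rnorm(4 * n, sd = 0.05), n, 4)
  sc <- pca_baseline(x, n_components = 2)
  expect_equal(dim(sc), c(n, 2))
  z <- scale(x)
  ev <- eigen(cov(z))$vectors[, 1:2]
  oracle <- z %*% ev
  expect_gte(abs(cor(sc[, 1], oracle[, 1])), 1 - 1e-9)
  expect_gte(abs(cor(sc[, 2], oracle[, 2])), 1 - 1e-9)

  one <- cbind(v = rnorm(10), w = rep(1, 10)) # one informative column
  expect_equal(ncol(pca_baseline(one, 1)), 1)
  expect_error(pca_baseline(one, 2), "rank")
  expect_error(pca_baseline(x, 0), ">= 1")
})
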