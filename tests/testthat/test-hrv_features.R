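test_that("time-domain features match hand arithmetic", {
  const <- hrv_time_domain(c(800, 800, 800))
  expect_equal(unname(const[c("MEAN", "VAR", "SDNN", "RMSSD", "SDSD",
                              "PNN50", "CV")]),
               c(800, 0, 0, 0, 0, 0, 0))
  expect_equal(unname(const[c("MAX", "MIN")]), c(800, 800))

  v <- hrv_time_domain(c(800, 810, 790))
  expect_equal(unname(v["RMSSD"]), sqrt((10^2 + 20^2) / 2), tolerance = 1e-12)
  # diffs 10, -20: mean -5, population sd 15
  expect_equal(unname(v["SDSD"]), 15)
  expect_equal(unname(v["PNN50"]), 0)

  p <- hrv_time_domain(c(800, 860, 865)) # diffs 60, 5
  expect_equal(unname(p["PNN50"]), 50)
})

test_that("RMSSD^2 equals SDSD^2 plus squared mean difference", {
  set.seed(31)
  for (i in 1:50) {
    rr <- runif(sample(3:200, 1), 500, 1200)
    f <- hrv_time_domain(rr)
    expect_equal(f[["RMSSD"]]^2,
                 f[["SDSD"]]^2 + mean(diff(rr))^2,
                 tolerance = 1e-9)
  }
})

test_that("features scale correctly under rr -> c * rr", {
  set.seed(7)
  rr <- 800 + cumsum(rnorm(300, 0, 10))
  t <- cumsum(c(0, rr[-300])) / 1000
  c0 <- 1.37
  a <- hrv_features(rr, beat_times = t)
  b <- hrv_features(rr * c0, beat_times = t)
  lin <- c("MEAN", "MAX", "MIN", "SDNN", "RMSSD", "SDSD")
  expect_equal(unname(b[lin]), unname(a[lin] * c0), tolerance = 1e-9)
  expect_equal(b[["VAR"]], a[["VAR"]] * c0^2, tolerance = 1e-9)
  for (inv in c("CV", "DFA", "LFHF"))
    expect_equal(b[[inv]], a[[inv]], tolerance = 1e-6)
})

test_that("spectral power concentrates in the driven band", {
  t <- seq(0, 300, by = 0.8)
  lf <- hrv_freq_domain(800 + 50 * sin(2 * pi * 0.10 * t), beat_times = t)
  expect_gte(lf[["LF"]] / lf[["TP"]], 0.90)

  hf <- hrv_freq_domain(800 + 50 * sin(2 * pi * 0.25 * t), beat_times = t)
  expect_gt(hf[["HF"]], hf[["LF"]])
  expect_lt(hf[["LFHF"]], 0.2)
})

test_that("a constant tachogram has zero band powers", {
  t <- seq(0, 300, by = 0.8)
  f <- hrv_freq_domain(rep(800, length(t)), beat_times = t)
  expect_equal(unname(f[c("VLF", "LF", "HF", "VHF", "TP")]), rep(0, 5))
  expect_true(is.na(f[["LFHF"]]))
})

test_that("band powers are non-negative and bounded by total power", {
  set.seed(12)
  for (i in 1:10) {
    n <- 400
    rr <- 850 + rnorm(n, 0, 40)
    t <- cumsum(c(0, rr[-n])) / 1000
    f <- hrv_freq_domain(rr, beat_times = t)
    bands <- f[c("VLF", "LF", "HF", "VHF")]
    expect_true(all(bands >= 0))
    expect_lte(sum(bands), f[["TP"]] * 1.001 + 1e-9)
  }
})

test_that("DFA of white noise scales with exponent near one half", {
  # the short-range boxes carry a small positive finite-size bias, so the
  # Monte-Carlo mean (not each draw) is held to 0.5 +/- 0.1
  set.seed(99)
  alphas <- replicate(10, dfa_alpha(rnorm(1000, 800, 30)))
  expect_lte(abs(mean(alphas) - 0.5), 0.1)
  expect_true(all(alphas > 0.35 & alphas < 0.75))
  # and strongly correlated noise scores clearly higher
  set.seed(100)
  rw <- 800 + cumsum(rnorm(1000, 0, 5))
  expect_gt(dfa_alpha(rw), mean(alphas) + 0.4)
})

test_that("Renyi entropy is zero for constant input and ln(bins) at uniform", {
  expect_equal(renyi_entropy(rep(800, 50)), 0)
  vals <- rep(seq(0.05, 0.95, by = 0.1), each = 5)
  expect_equal(renyi_entropy(vals, n_bins = 10), log(10), tolerance = 1e-12)
})

test_that("sample entropy equals the brute-force template-match oracle", {
  set.seed(55)
  for (i in 1:12) {
    n <- sample(100:300, 1)
    x <- 800 + rnorm(n, 0, 30)
    r <- 0.2 * sd(x)
    expect_identical(sample_entropy(x, m = 2, r = r),
                     sampen_brute(x, 2, r))
  }
  # strict periodicity: matches always extend, SampEn 0
  per <- rep(c(800, 900), 100)
  expect_equal(sample_entropy(per), 0)
  expect_equal(sampen_brute(per, 2, 0.2 * sd(per)), 0)
})

test_that("degenerate nonlinear inputs follow the documented conventions", {
  expect_equal(sample_entropy(rep(800, 200)), 0) # zero variance
  expect_true(is.na(dfa_alpha(rep(800, 200))))
  expect_true(is.na(sample_entropy(rnorm(50)))) # below min length
})

test_that("the assembled 18-vector is named and ordered canonically", {
  rr <- cached("rr8h", simulate_subject("mild", synthetic_config(),
                                        seed = 2)$rr)
  seg <- hrvpyramid:::rr_window(rr, 0, 300)
  f <- hrv_features(seg$rr_ms, beat_times = seg$beat_times[-length(seg$beat_times)])
  expect_identical(names(f), hrv_feature_names)
  expect_true(all(is.finite(f)))
  expect_true(f[["MIN"]] <= f[["MEAN"]] && f[["MEAN"]] <= f[["MAX"]])
  expect_gte(f[["TP"]], max(f[c("VLF", "LF", "HF", "VHF")]))
})
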