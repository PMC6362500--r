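# Independent reference implementations used as oracles.

# brute-force O(n^2) sample entropy by explicit template matching
sampen_brute <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

# histogram entropy via graphics::hist (independent binning path)
entropy_hist <- function(v, bins = 10) {
  if (diff(range(v)) == 0) return(0)
  h <- hist(v, breaks = seq(min(v), max(v), length.out = bins + 1),
            plot = FALSE, include.lowest = TRUE, right = TRUE)
  p <- h$counts / length(v)
  p <- p[p > 0]
  -sum(p * log(p))
}

# exhaustive k selection: pool every subject at every k by explicit
# sort-and-mean, score with entropy_hist, take the smallest argmax
select_k_brute <- function(pools, bins = 10) {
  kmax <- min(lengths(pools))
  h <- vapply(seq_len(kmax), function(k) {
    pooled <- vapply(pools, function(p)
      mean(sort(p, decreasing = TRUE)[1:k]), numeric(1))
    entropy_hist(pooled, bins)
  }, numeric(1))
  list(k = which.max(h), curve = h)
}

# Welch band power of a signal, for denoising checks
band_power <- function(x, fs, lo, hi, nperseg = 4096) {
  w <- hrvpyramid:::welch_psd(x - mean(x), fs, nperseg)
  i <- w$freq >= lo & w$freq <= hi
  pracma::trapz(w$freq[i], w$psd[i])
}
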