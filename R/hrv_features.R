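#' Time-domain HRV features
#'
#' The nine classical time-domain statistics of an RR segment. Variance
#' (and hence SDNN and CV) uses the population definition (denominator
#' `n`), as do the successive-difference statistics, so that the identity
#' `RMSSD^2 = SDSD^2 + mean(diff(rr))^2` holds exactly.
#'
#' @param rr_ms Numeric vector of RR intervals in ms.
#' @return Named numeric vector: `MEAN`, `VAR` (ms^2), `MAX`, `MIN`,
#'   `SDNN`, `RMSSD`, `SDSD` (ms), `PNN50` (percent of successive
#'   differences exceeding 50 ms), `CV` (SDNN/MEAN, dimensionless).
#'   Features whose precondition is unmet (fewer than 2 intervals; fewer
#'   than 3 for difference statistics) are `NA`.
#' @examples
#' hrv_time_domain(c(800, 810, 790))
#' @export
hrv_time_domain <- function(rr_ms) {
  out <- stats::setNames(rep(NA_real_, 9L),
                         c("MEAN", "VAR", "MAX", "MIN", "SDNN", "RMSSD",
                           "SDSD", "PNN50", "CV"))
  n <- length(rr_ms)
  if (n >= 2L) {
    m <- mean(rr_ms)
    v <- mean((rr_ms - m)^2) # population variance
    out["MEAN"] <- m
    out["VAR"] <- v
    out["MAX"] <- max(rr_ms)
    out["MIN"] <- min(rr_ms)
    out["SDNN"] <- sqrt(v)
    out["CV"] <- sqrt(v) / m
  }
  if (n >= 3L) {
    d <- diff(rr_ms)
    out["RMSSD"] <- sqrt(mean(d^2))
    out["SDSD"] <- sqrt(mean((d - mean(d))^2))
    out["PNN50"] <- 100 * mean(abs(d) > 50)
  }
  out
}

# Welch power spectral density: Hann window, 50% overlap, one-sided.
# Returns power per Hz so that band integrals are in input-units^2.
welch_psd <- function(x, fs, nperseg = 256L, overlap = 0.5) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  i <- seq_len(nperseg) - 1L
  w <- 0.5 - 0.5 * cos(2 * pi * i / (nperseg - 1)) # Hann
  u <- sum(w^2)
  nf <- nperseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- stats::fft(seg)[seq_len(nf)]
    acc <- acc + Mod(sp)^2
  }
  psd <- acc / (length(starts) * u * fs)
  if (nf > 2L) psd[2:(nf - 1L)] <- 2 * psd[2:(nf - 1L)]
  if (nperseg %% 2L == 1L) psd[nf] <- 2 * psd[nf]
  list(freq = (seq_len(nf) - 1L) * fs / nperseg, psd = psd)
}

#' Frequency-domain HRV features
#'
#' The tachogram (RR interval versus beat time) is resampled to an even
#' grid by cubic spline interpolation at `fs_resample` Hz, its power
#' spectral density estimated by Welch's method (Hann window, segments of
#' at most 256 samples, 50% overlap), and band powers obtained by
#' trapezoidal integration of the PSD over the standard HRV bands:
#' VLF 0.003–0.04, LF 0.04–0.15, HF 0.15–0.40, VHF 0.40–0.50 Hz. Total
#' power (TP) spans 0.003–0.50 Hz and `LFHF = LF/HF`.
#'
#' @param rr_ms RR intervals in ms.
#' @param beat_times Onset time (s) of each interval relative to the
#'   segment start; derived from the cumulative interval sum when `NULL`.
#' @param fs_resample Tachogram resampling rate in Hz (default 4).
#' @param bands Numeric vector of the five band edges in Hz.
#' @return Named numeric vector `VLF`, `LF`, `HF`, `VHF`, `TP` (ms^2) and
#'   `LFHF`. A constant tachogram yields all-zero band powers and `LFHF`
#'   `NA`; `LFHF` is `NA` with a warning when HF = 0. Segments shorter
#'   than 60 s return `NA` for all six values.
#' @examples
#' t <- seq(0, 300, by = 0.8)
#' rr <- 800 + 50 * sin(2 * pi * 0.10 * t)
#' f <- hrv_freq_domain(rr, beat_times = t)
#' f["LF"] / f["TP"] # close to 1: all power in the LF band
#' @export
hrv_freq_domain <- function(rr_ms, beat_times = NULL, fs_resample = 4,
                            bands = c(0.003, 0.04, 0.15, 0.40, 0.50)) {
  nms <- c("VLF", "LF", "HF", "VHF", "TP", "LFHF")
  out <- stats::setNames(rep(NA_real_, 6L), nms)
  if (length(bands) != 5L || any(diff(bands) <= 0))
    stop("`bands` must be 5 increasing edges (VLF lo, LF lo, HF lo, VHF lo, VHF hi)")
  n <- length(rr_ms)
  if (is.null(beat_times)) beat_times <- cumsum(c(0, rr_ms[-n])) / 1000
  span <- beat_times[n] - beat_times[1]
  if (n < 4L || span < 60) return(out)
  if (stats::var(rr_ms) == 0) {
    out[c("VLF", "LF", "HF", "VHF", "TP")] <- 0
    return(out)
  }
  f <- stats::splinefun(beat_times, rr_ms, method = "natural")
  tg <- seq(beat_times[1], beat_times[n], by = 1 / fs_resample)
  x <- f(tg)
  ps <- welch_psd(x - mean(x), fs_resample)
  band_power <- function(lo, hi) {
    idx <- which(ps$freq >= lo & ps$freq <= hi)
    if (length(idx) < 2L) return(0)
    pracma::trapz(ps$freq[idx], ps$psd[idx])
  }
  out["VLF"] <- band_power(bands[1], bands[2])
  out["LF"]  <- band_power(bands[2], bands[3])
  out["HF"]  <- band_power(bands[3], bands[4])
  out["VHF"] <- band_power(bands[4], bands[5])
  out["TP"]  <- band_power(bands[1], bands[5])
  if (out["HF"] > 0) out["LFHF"] <- out["LF"] / out["HF"]
  else warning("HF power is zero: LF/HF undefined")
  out
}

#' Detrended fluctuation analysis scaling exponent (alpha-1)
#'
#' The RR series is mean-centred and integrated; for each box size the
#' integrated profile is split into non-overlapping boxes, linearly
#' detrended per box, and the root-mean-square fluctuation computed. The
#' exponent is the slope of log F(s) against log s over the short-range
#' boxes 4–16 (alpha-1). White noise gives alpha near 0.5, 1/f processes
#' near 1.
#'
#' @param rr_ms RR intervals in ms (at least `min_n`, default 100).
#' @param scales Integer box sizes (default `4:16`).
#' @param min_n Minimum series length.
#' @return The scaling exponent, or `NA` for short or zero-variance input.
#' @export
dfa_alpha <- function(rr_ms, scales = 4:16, min_n = 100L) {
  n <- length(rr_ms)
  if (n < min_n || stats::var(rr_ms) == 0) return(NA_real_)
  y <- cumsum(rr_ms - mean(rr_ms))
  fl <- vapply(scales, function(s) {
    nb <- n %/% s
    if (nb < 2L) return(NA_real_)
    m <- matrix(y[seq_len(nb * s)], nrow = s)
    tc <- seq_len(s) - (s + 1) / 2
    beta <- colSums(m * tc) / sum(tc^2)
    res <- m - outer(tc, beta)
    res <- sweep(res, 2L, colMeans(m))
    sqrt(mean(res^2))
  }, numeric(1))
  ok <- is.finite(fl) & fl > 0
  if (sum(ok) < 2L) return(NA_real_)
  unname(stats::coef(stats::lm(log(fl[ok]) ~ log(scales[ok])))[2])
}

#' Renyi entropy of order 2 of the RR interval distribution
#'
#' Collision entropy `-log(sum p^2)` of a 10-bin equal-width histogram of
#' the segment's intervals (natural log). A constant segment puts all mass
#' in one bin and returns 0.
#'
#' @param rr_ms RR intervals in ms (length >= 2).
#' @param n_bins Number of histogram bins (default 10).
#' @param order Entropy order q (default 2).
#' @return The Renyi entropy (nats).
#' @export
renyi_entropy <- function(rr_ms, n_bins = 10L, order = 2) {
  if (length(rr_ms) < 2L) return(NA_real_)
  rng <- range(rr_ms)
  if (rng[1] == rng[2]) return(0)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  cnt <- tabulate(findInterval(rr_ms, edges, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = n_bins)
  p <- cnt / sum(cnt)
  p <- p[p > 0]
  if (order == 1) return(-sum(p * log(p)))
  log(sum(p^order)) / (1 - order)
}

#' Sample entropy of an RR segment
#'
#' SampEn(m, r): the negative logarithm of the conditional probability
#' that two sequences matching for `m` points (Chebyshev distance within
#' `r`) also match for `m + 1` points, self-matches excluded. Defaults
#' m = 2, r = 0.2 times the segment's (population) standard deviation. A
#' zero-variance segment returns 0. For very long segments the statistic
#' is evaluated on the first `max_n` intervals (default 2000), where the
#' estimator has long since converged, keeping the quadratic-cost kernel
#' bounded.
#'
#' @param rr_ms RR intervals in ms.
#' @param m Template length (default 2).
#' @param r Tolerance; default `0.2 * sd` of the (possibly truncated)
#'   segment.
#' @param min_n Minimum length (default 100) below which `NA` is returned.
#' @param max_n Evaluation cap (default 2000).
#' @return Sample entropy (nats); `NA` when no template pair matches.
#' @export
sample_entropy <- function(rr_ms, m = 2L, r = NULL, min_n = 100L,
                           max_n = 2000L) {
  n <- length(rr_ms)
  if (n < min_n) return(NA_real_)
  if (n > max_n) rr_ms <- rr_ms[seq_len(max_n)]
  if (is.null(r)) {
    sdev <- sqrt(mean((rr_ms - mean(rr_ms))^2))
    if (sdev == 0) return(0)
    r <- 0.2 * sdev
  }
  sampen_cpp(as.numeric(rr_ms), as.integer(m), as.numeric(r))
}

#' Nonlinear HRV features
#'
#' @param rr_ms RR intervals in ms.
#' @param sampen_m,sampen_r SampEn parameters (see [sample_entropy()]).
#' @param dfa_scales DFA box sizes (see [dfa_alpha()]).
#' @param renyi_bins,renyi_order Renyi histogram parameters.
#' @return Named numeric vector `DFA`, `RENYI`, `SAMPEN`.
#' @export
hrv_nonlinear <- function(rr_ms, sampen_m = 2L, sampen_r = NULL,
                          dfa_scales = 4:16, renyi_bins = 10L,
                          renyi_order = 2) {
  c(DFA = dfa_alpha(rr_ms, scales = dfa_scales),
    RENYI = renyi_entropy(rr_ms, n_bins = renyi_bins, order = renyi_order),
    SAMPEN = sample_entropy(rr_ms, m = sampen_m, r = sampen_r))
}

#' The full 18-feature HRV vector of one RR segment
#'
#' Concatenates [hrv_time_domain()], [hrv_freq_domain()] and
#' [hrv_nonlinear()] in the canonical order of [hrv_feature_names].
#'
#' @param rr_ms RR intervals in ms.
#' @param beat_times Interval onset times in seconds (optional; see
#'   [hrv_freq_domain()]).
#' @param ... Passed to the domain-specific functions.
#' @return Named numeric vector of length 18.
#' @export
hrv_features <- function(rr_ms, beat_times = NULL, ...) {
  dots <- list(...)
  pick <- function(f) dots[names(dots) %in% names(formals(f))]
  td <- hrv_time_domain(rr_ms)
  fd <- do.call(hrv_freq_domain,
                c(list(rr_ms = rr_ms, beat_times = beat_times),
                  pick(hrv_freq_domain)))
  nl <- do.call(hrv_nonlinear, c(list(rr_ms = rr_ms), pick(hrv_nonlinear)))
  out <- c(td, fd, nl)
  out[hrv_feature_names]
}
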