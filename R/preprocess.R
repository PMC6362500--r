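#' Wavelet denoising of an ECG signal
#'
#' MODWT shrinkage with the Daubechies-6 basis: the decomposition is taken
#' deep enough that the coarsest approximation band lies below 0.5 Hz at
#' the record's sampling rate; that approximation (baseline wander) is
#' zeroed, and the finest detail level (high-frequency noise, upper half of
#' the spectrum) is soft-thresholded with the universal threshold
#' \eqn{\hat\sigma \sqrt{2 \log n}}, \eqn{\hat\sigma} from the MAD of the
#' finest-level coefficients. Everything in between — including the 5–15 Hz
#' QRS band — passes through untouched. The signal is reflection-padded
#' before the circular transform so record edges are not contaminated.
#'
#' @param ecg An [ecg_signal()].
#' @param max_level Decomposition depth. Default: smallest J with
#'   `fs / 2^(J+1) <= 0.5` Hz (e.g. 7 at 128 Hz, 8 at 250 Hz).
#' @param threshold_finest Soft-threshold the finest detail level
#'   (default `TRUE`).
#' @return Denoised [ecg_signal()] of identical length and sampling rate.
#' @export
wavelet_denoise <- function(ecg, max_level = NULL, threshold_finest = TRUE) {
  stopifnot(inherits(ecg, "ecg_signal"))
  x <- ecg$samples
  n <- length(x)
  if (is.null(max_level)) {
    max_level <- 1L
    while (ecg$fs / 2^(max_level + 1) > 0.5) max_level <- max_level + 1L
  }
  if (n < 2^max_level)
    stop("signal too short for level ", max_level,
         "; maximum feasible level is ", max(1L, floor(log2(n))))
  pad <- min(n, 2^(max_level - 1) * (length(.db6_g) - 1L))
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[(n - pad + 1L):n]))
  dec <- modwt_db6(xp, max_level)
  dec$V[] <- 0 # drop baseline-band approximation (< 0.5 Hz)
  if (threshold_finest) {
    w1 <- dec$W[, 1]
    sig <- stats::median(abs(w1 - stats::median(w1))) / 0.6745
    thr <- sig * sqrt(2 * log(length(w1)))
    dec$W[, 1] <- sign(w1) * pmax(abs(w1) - thr, 0)
  }
  y <- imodwt_db6(dec)[pad + seq_len(n)]
  ecg_signal(y, fs = ecg$fs, record_id = ecg$record_id, t0 = ecg$t0)
}

#' Detect R peaks with a fixed sliding window and adaptive threshold
#'
#' A candidate R peak is a local maximum that (a) exceeds an adaptive
#' amplitude threshold — 0.5 times the `quantile_level` amplitude quantile
#' of its surrounding 10-second block — and (b) is the largest sample
#' within its `window_s`-wide sliding window. Peaks closer than
#' `refractory_s` to the previously accepted peak are suppressed (the
#' larger of the two wins), mirroring the physiological refractory period
#' of the myocardium.
#'
#' The quantile is taken high (default 0.995) because the positive QRS
#' lobe occupies only a few percent of the samples at normal heart rates:
#' half of the top half-percent amplitude tracks half the R amplitude,
#' whereas lower quantiles sit in the noise floor between beats.
#'
#' @param ecg A denoised [ecg_signal()]; sampling rates of 100 Hz and up
#'   are recommended.
#' @param window_s Sliding-window width in seconds (default 0.8).
#' @param refractory_s Minimum peak spacing in seconds (default 0.25).
#' @param block_s Width of the threshold-estimation blocks (default 10).
#' @param quantile_level Quantile of the block amplitude distribution used
#'   for the adaptive threshold (default 0.995).
#' @return Integer vector of 1-based sample indices, strictly increasing.
#'   A flat (zero-variance) signal yields an empty result with a warning.
#' @export
detect_r_peaks <- function(ecg, window_s = 0.8, refractory_s = 0.25,
                           block_s = 10, quantile_level = 0.995) {
  stopifnot(inherits(ecg, "ecg_signal"))
  x <- ecg$samples
  fs <- ecg$fs
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0) {
    warning("flat signal: no R peaks detected")
    return(integer(0))
  }
  block <- pmin(((seq_len(n) - 1L) %/% max(1L, round(block_s * fs))) + 1L,
                .Machine$integer.max)
  thr_by_block <- tapply(x, block, function(b)
    0.5 * stats::quantile(b, quantile_level, names = FALSE))
  thr <- thr_by_block[block]
  is_max <- c(TRUE, x[-1] > x[-n]) & c(x[-n] >= x[-1], TRUE)
  cand <- which(is_max & x >= thr & x > 0)
  if (!length(cand)) return(integer(0))
  half <- max(1L, round(window_s * fs / 2))
  keep <- vapply(cand, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    x[i] >= max(x[lo:hi])
  }, logical(1))
  cand <- cand[keep]
  if (!length(cand)) return(integer(0))
  ref <- refractory_s * fs
  out <- cand[1]
  for (i in cand[-1]) {
    last <- out[length(out)]
    if (i - last >= ref) out <- c(out, i)
    else if (x[i] > x[last]) out[length(out)] <- i
  }
  as.integer(out)
}

#' RR intervals from detected peak indices
#'
#' @param peak_indices Strictly increasing 1-based sample indices (at
#'   least 2).
#' @param fs Sampling rate in Hz.
#' @return An [rr_series()] with `rr_ms[i] = (idx[i+1] - idx[i]) / fs * 1000`
#'   and beat times `(idx - idx[1]) / fs` seconds.
#' @export
rr_from_peaks <- function(peak_indices, fs) {
  if (length(peak_indices) < 2L)
    stop("need at least 2 peaks to form RR intervals")
  if (any(diff(peak_indices) <= 0))
    stop("peak indices must be strictly increasing")
  if (fs <= 0) stop("fs must be positive")
  bt <- (peak_indices - peak_indices[1]) / fs
  rr_series(beat_times = bt)
}

#' Detect and correct erroneous RR intervals
#'
#' Artifact rule for Holter RR series: an interval is flagged when it falls
#' outside `[low_ms, high_ms]` (defaults 300–2000 ms, outside plausible
#' sinus rhythm) or deviates more than `max_dev` (default 20%) from the
#' centred `med_win`-beat (default 11) rolling median. Flagged intervals
#' are replaced by that local median and marked `"corrected"`; beat times
#' are rebuilt from the corrected intervals so the series invariants hold.
#' The operation is idempotent.
#'
#' @param rr An [rr_series()].
#' @param low_ms,high_ms Physiological interval bounds in ms.
#' @param max_dev Maximal relative deviation from the rolling median.
#' @param med_win Rolling-median window in beats (odd).
#' @param max_flag_frac If more than this fraction of intervals is flagged
#'   (default 0.2) the record is considered unusable and an error advising
#'   rejection is raised.
#' @return Corrected [rr_series()] with updated `quality_flags`.
#' @export
correct_rr <- function(rr, low_ms = 300, high_ms = 2000, max_dev = 0.2,
                       med_win = 11L, max_flag_frac = 0.2) {
  stopifnot(inherits(rr, "rr_series"))
  x <- rr$rr_ms
  n <- length(x)
  if (n == 0L) stop("empty RR series")
  k <- min(med_win, if (n %% 2L == 1L) n else n - 1L)
  med <- if (k >= 3L) stats::runmed(x, k, endrule = "median") else rep(stats::median(x), n)
  flag <- x < low_ms | x > high_ms | abs(x - med) > max_dev * med
  if (mean(flag) > max_flag_frac)
    stop(sprintf(
      "%.1f%% of intervals flagged as artifacts (limit %.0f%%): record should be rejected",
      100 * mean(flag), 100 * max_flag_frac))
  if (any(flag)) {
    # replacement = median of nearby unflagged intervals, so an outlier at
    # a series edge is never replaced by itself
    good <- which(!flag)
    if (!length(good))
      stop("no plausible intervals left after flagging: record should be rejected")
    half <- max(1L, (med_win - 1L) %/% 2L)
    for (i in which(flag)) {
      nb <- good[abs(good - i) <= half]
      if (!length(nb)) nb <- good[order(abs(good - i))][seq_len(min(5L, length(good)))]
      x[i] <- stats::median(x[nb])
    }
  }
  flags <- rr$quality_flags
  flags[flag] <- "corrected"
  rr_series(beat_times = rr$beat_times[1] + cumsum(c(0, x)) / 1000,
            rr_ms = x, quality_flags = flags, record_id = rr$record_id)
}

#' Extract the overnight analysis window from an RR series
#'
#' When the record carries a clock time for its first beat (`t0`, seconds
#' since midnight), the window from `start_clock` (default 22:00) to
#' `start_clock + duration_min` is cut; otherwise the first
#' `duration_min` minutes are taken and a warning is issued. Beat times of
#' the result are re-zeroed at the window start.
#'
#' @param rr An [rr_series()].
#' @param t0 Clock time of the first beat, seconds since midnight, or
#'   `NULL`.
#' @param start_clock Window start as seconds since midnight (default
#'   22 * 3600).
#' @param duration_min Window length in minutes (default 480 = 8 h).
#' @return An [rr_series()] covering the window.
#' @export
extract_sleep_window <- function(rr, t0 = NULL, start_clock = 22 * 3600,
                                 duration_min = 480) {
  stopifnot(inherits(rr, "rr_series"))
  if (is.null(t0)) {
    warning("no clock time available: taking the first ", duration_min,
            " minutes as the overnight window")
    start_s <- 0
  } else {
    offset <- (start_clock - t0) %% 86400
    start_s <- offset
  }
  rr_window(rr, start_s, start_s + duration_min * 60)
}

# subset an rr_series to intervals whose onset beat lies in [start_s, end_s);
# beat times re-zeroed at start_s
rr_window <- function(rr, start_s, end_s) {
  onset <- rr$beat_times[-length(rr$beat_times)]
  idx <- which(onset >= start_s & onset < end_s)
  if (length(idx) < 2L)
    stop("window [", start_s, ", ", end_s, ") contains fewer than 2 beats")
  rr_series(rr_ms = rr$rr_ms[idx],
            quality_flags = rr$quality_flags[idx],
            record_id = rr$record_id)
}
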