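#' Configuration of the synthetic overnight cohort generator
#'
#' Class-conditional targets encode the literature direction — HRV is
#' depressed as hypertension worsens while sympathovagal (LF/HF) balance
#' shifts up: mild (mean RR 900 ms, SDNN 55 ms, LF/HF 1.5), moderate
#' (850 ms, 40 ms, 2.5), severe (800 ms, 25 ms, 4.0). The tachogram model
#' is two sinusoidal oscillators (LF at 0.10 Hz, HF at 0.25 Hz) plus white
#' Gaussian noise scaled so the total variance hits the SDNN target; the
#' oscillator amplitude ratio is `sqrt(LF/HF target)`. Per-subject
#' physiological heterogeneity is introduced by jittering each subject's
#' targets with coefficient of variation `subject_cv`.
#'
#' @param mean_rr,sdnn_target Named per-class vectors (ms).
#' @param lfhf_target Named per-class LF/HF balance targets.
#' @param osc_frac Fraction of the target variance carried by the two
#'   oscillators together (default 0.45; the rest is broadband noise).
#' @param lf_freq,hf_freq Oscillator frequencies in Hz.
#' @param artifact_rate Fraction of beats perturbed into
#'   ectopic-like/blocked-like spikes, in `[0, 0.2]`.
#' @param duration Record duration in minutes (default 480 = 8 h).
#' @param subject_cv Coefficient of variation of the per-subject target
#'   jitter (default 0.12).
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    mean_rr = c(mild = 900, moderate = 850, severe = 800),
    sdnn_target = c(mild = 55, moderate = 40, severe = 25),
    lfhf_target = c(mild = 1.5, moderate = 2.5, severe = 4.0),
    osc_frac = 0.45,
    lf_freq = 0.10, hf_freq = 0.25,
    artifact_rate = 0, duration = 480, subject_cv = 0.12) {
  for (v in list(mean_rr, sdnn_target, lfhf_target)) {
    if (!all(severity_levels %in% names(v)))
      stop("per-class parameters need entries mild, moderate, severe")
    if (any(v <= 0)) stop("per-class parameters must be positive")
  }
  if (artifact_rate < 0 || artifact_rate > 0.2)
    stop("artifact_rate must lie in [0, 0.2]")
  if (duration < 10) stop("duration must be at least 10 minutes")
  if (osc_frac <= 0 || osc_frac >= 1)
    stop("osc_frac must lie strictly between 0 and 1")
  structure(
    list(mean_rr = mean_rr, sdnn_target = sdnn_target,
         lfhf_target = lfhf_target, osc_frac = osc_frac,
         lf_freq = lf_freq, hf_freq = hf_freq,
         artifact_rate = artifact_rate, duration = duration,
         subject_cv = subject_cv),
    class = "synthetic_config"
  )
}

#' Simulate one subject's overnight RR series
#'
#' Beats are laid down sequentially: `rr(t) = mean_rr + A_lf sin(2 pi
#' f_lf t) + A_hf sin(2 pi f_hf t + phi) + e`, with `e` white Gaussian
#' noise scaled so the total variance matches the (subject-jittered) SDNN
#' target and the oscillator amplitudes split `osc_frac` of that variance
#' in the configured LF/HF ratio. A fraction `artifact_rate` of beats is
#' then replaced by ectopic-like spikes (interval shortened to 45%) or
#' block-like pauses (lengthened to 220%). Fully determined by `seed`.
#'
#' @param severity `"mild"`, `"moderate"` or `"severe"`.
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @param subject_id Identifier stored on the series.
#' @return List with `rr` (the [rr_series()] including artifacts),
#'   `clean_rr` (before artifact injection), `artifact_idx` (perturbed
#'   interval indices), `severity`, `targets` (the jittered per-subject
#'   targets).
#' @export
simulate_subject <- function(severity, config = synthetic_config(),
                             seed = 1L, subject_id = NULL) {
  severity <- match.arg(severity, severity_levels)
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(subject_id)) subject_id <- paste0(severity, "_", seed)
  set.seed(seed)
  jit <- function(x) x * max(0.5, 1 + stats::rnorm(1, 0, config$subject_cv))
  mu <- jit(config$mean_rr[[severity]])
  sdnn <- jit(config$sdnn_target[[severity]])
  lfhf <- jit(config$lfhf_target[[severity]])
  # split osc_frac of the variance between the two oscillators so that
  # lf_power / hf_power = lfhf (sinusoid power = A^2 / 2)
  var_total <- sdnn^2
  var_osc <- config$osc_frac * var_total
  var_hf <- var_osc / (1 + lfhf)
  var_lf <- var_osc - var_hf
  a_lf <- sqrt(2 * var_lf)
  a_hf <- sqrt(2 * var_hf)
  var_noise <- var_total - var_osc
  if (var_noise < 0)
    stop("sdnn_target below the oscillator contribution: unreachable")
  phi <- stats::runif(1, 0, 2 * pi)
  # overshoot by a minute so artifact correction cannot leave the series
  # short of the nominal duration
  total_s <- config$duration * 60 + 60
  n_max <- ceiling(total_s / (mu / 1000) * 1.3) + 10L
  noise <- stats::rnorm(n_max, 0, sqrt(var_noise))
  t <- 0
  rr <- numeric(n_max)
  bt <- numeric(n_max)
  i <- 0L
  while (t < total_s && i < n_max) {
    i <- i + 1L
    bt[i] <- t
    val <- mu + a_lf * sin(2 * pi * config$lf_freq * t) +
      a_hf * sin(2 * pi * config$hf_freq * t + phi) + noise[i]
    val <- max(val, 250) # keep the grid physical even in the noise tails
    rr[i] <- val
    t <- t + val / 1000
  }
  rr <- rr[seq_len(i)]
  clean <- rr_series(rr_ms = rr, record_id = subject_id)
  artifact_idx <- integer(0)
  if (config$artifact_rate > 0) {
    n_art <- round(config$artifact_rate * length(rr))
    if (n_art > 0) {
      artifact_idx <- sort(sample(seq_along(rr), n_art))
      stretch <- ifelse(stats::runif(n_art) < 0.5, 0.45, 2.2)
      rr[artifact_idx] <- rr[artifact_idx] * stretch
    }
  }
  list(rr = rr_series(rr_ms = rr, record_id = subject_id),
       clean_rr = clean, artifact_idx = artifact_idx,
       severity = severity,
       targets = c(mean_rr = mu, sdnn = sdnn, lfhf = lfhf))
}

#' Simulate a severity-labelled cohort
#'
#' `n_per_class` subjects per severity class, each with an overnight RR
#' series and a [subject_record()] whose SBP/DBP are drawn uniformly from
#' the guideline row(s) matching the class, so [assign_severity()]
#' round-trips the label by construction.
#'
#' @param n_per_class Subjects per class (>= 1).
#' @param config A [synthetic_config()].
#' @param seed Integer master seed; per-subject seeds are derived from it.
#' @return List of per-subject lists: the [simulate_subject()] output plus
#'   `record` (a [subject_record()]).
#' @export
simulate_cohort <- function(n_per_class = 30L, config = synthetic_config(),
                            seed = 42L) {
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  out <- list()
  sidx <- 0L
  for (cl in severity_levels) {
    for (i in seq_len(n_per_class)) {
      sidx <- sidx + 1L
      sid <- sprintf("%s_%02d", cl, i)
      sub <- simulate_subject(cl, config, seed = (seed * 131L + sidx) %% 2147483647L,
                              subject_id = sid)
      set.seed((seed * 131L + sidx) %% 2147483647L + 7L)
      bp <- switch(cl,
        mild = c(stats::runif(1, 95, 119), stats::runif(1, 60, 79)),
        moderate = c(stats::runif(1, 120, 159), stats::runif(1, 80, 99)),
        severe = c(stats::runif(1, 160, 200), stats::runif(1, 100, 120))
      )
      sub$record <- subject_record(sid, sbp = bp[1], dbp = bp[2],
                                   severity = cl)
      out[[sid]] <- sub
    }
  }
  out
}

#' Synthesize an ECG waveform from an RR series
#'
#' Places a template QRS complex — a Ricker (negative second derivative of
#' a Gaussian) wavelet of width `qrs_sigma`, peak amplitude 1 mV — at
#' every beat time, then adds optional sinusoidal baseline drift and white
#' measurement noise. Intended for exercising the denoise/detect/extract
#' chain against known ground truth.
#'
#' @param rr An [rr_series()].
#' @param fs Sampling rate in Hz (>= 100).
#' @param qrs_sigma Template width parameter in seconds (default 0.015).
#' @param drift_amp Baseline drift amplitude in mV (default 0.15).
#' @param drift_freq Drift frequency in Hz (default 0.3).
#' @param noise_sd White noise standard deviation in mV (default 0.01).
#' @param seed Seed for the noise (default 1).
#' @return An [ecg_signal()] covering the full beat span.
#' @export
synthesize_ecg <- function(rr, fs, qrs_sigma = 0.015, drift_amp = 0.15,
                           drift_freq = 0.3, noise_sd = 0.01, seed = 1L) {
  stopifnot(inherits(rr, "rr_series"))
  if (fs < 100) stop("fs must be at least 100 Hz for a usable QRS template")
  if (min(rr$rr_ms) / 1000 < 8 * qrs_sigma)
    stop("beats closer than the template width: reduce qrs_sigma")
  bt <- rr$beat_times - rr$beat_times[1]
  n <- floor(max(bt) * fs) + ceiling(8 * qrs_sigma * fs) + 1L
  x <- numeric(n)
  half <- ceiling(4 * qrs_sigma * fs)
  for (t in bt) {
    c_idx <- round(t * fs) + 1L
    lo <- max(1L, c_idx - half); hi <- min(n, c_idx + half)
    tt <- ((lo:hi) - c_idx) / fs
    z <- (tt / qrs_sigma)^2
    x[lo:hi] <- x[lo:hi] + (1 - z) * exp(-z / 2)
  }
  tgrid <- (seq_len(n) - 1L) / fs
  if (drift_amp > 0)
    x <- x + drift_amp * sin(2 * pi * drift_freq * tgrid)
  if (noise_sd > 0) {
    set.seed(seed)
    x <- x + stats::rnorm(n, 0, noise_sd)
  }
  ecg_signal(x, fs = fs, record_id = rr$record_id)
}
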