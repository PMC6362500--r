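#' ECG signal container
#'
#' A light S3 wrapper around a vector of voltage samples with its sampling
#' rate. All downstream operations (denoising, R-peak detection) consume
#' this type.
#'
#' @param samples Numeric vector of voltage samples (mV), all finite,
#'   length >= 1.
#' @param fs Sampling rate in Hz, > 0.
#' @param record_id Optional record identifier string.
#' @param t0 Optional clock time of the first sample, seconds since
#'   midnight (used to locate the overnight 22:00-06:00 window).
#' @return An object of class `ecg_signal` with elements `samples`, `fs`,
#'   `record_id`, `t0`.
#' @examples
#' ecg <- ecg_signal(sin(seq(0, 2 * pi, length.out = 250)), fs = 250)
#' length(ecg$samples)
#' @export
ecg_signal <- function(samples, fs, record_id = NA_character_, t0 = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("ECG signal must contain at least one sample")
  if (!all(is.finite(samples))) stop("ECG samples must all be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("sampling rate `fs` must be a single positive number")
  structure(
    list(samples = samples, fs = as.numeric(fs),
         record_id = record_id, t0 = t0),
    class = "ecg_signal"
  )
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal> %s: %d samples @ %g Hz (%.1f s)\n",
              ifelse(is.na(x$record_id), "unnamed", x$record_id),
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' RR-interval series container
#'
#' The pipeline's central object: strictly increasing beat times (seconds
#' from record start) and the intervals between consecutive beats in
#' milliseconds. The invariant `rr_ms[i] == (beat_times[i+1] -
#' beat_times[i]) * 1000` is enforced to 1e-6 ms; `length(rr_ms) ==
#' length(beat_times) - 1`.
#'
#' @param beat_times Numeric vector of beat times in seconds, strictly
#'   increasing. May be omitted, in which case times are accumulated from 0
#'   by the cumulative sum of `rr_ms`.
#' @param rr_ms Numeric vector of RR intervals in milliseconds, all > 0.
#'   May be omitted when `beat_times` is given.
#' @param quality_flags Optional character vector (one per interval) in
#'   `c("ok", "corrected", "removed-gap")`; defaults to all `"ok"`.
#' @param record_id Optional identifier.
#' @return Object of class `rr_series`.
#' @examples
#' rr <- rr_series(rr_ms = c(1000, 1000, 1000))
#' rr$beat_times # 0 1 2 3
#' @export
rr_series <- function(beat_times = NULL, rr_ms = NULL,
                      quality_flags = NULL, record_id = NA_character_) {
  if (is.null(beat_times) && is.null(rr_ms))
    stop("supply `beat_times` or `rr_ms`")
  if (is.null(beat_times)) {
    rr_ms <- as.numeric(rr_ms)
    beat_times <- cumsum(c(0, rr_ms)) / 1000
  } else if (is.null(rr_ms)) {
    beat_times <- as.numeric(beat_times)
    rr_ms <- diff(beat_times) * 1000
  } else {
    beat_times <- as.numeric(beat_times)
    rr_ms <- as.numeric(rr_ms)
  }
  n <- length(rr_ms)
  if (length(beat_times) != n + 1L)
    stop("length(beat_times) must equal length(rr_ms) + 1")
  if (!all(is.finite(beat_times)) || !all(is.finite(rr_ms)))
    stop("RR series values must be finite")
  if (any(rr_ms <= 0)) stop("all RR intervals must be positive")
  if (any(diff(beat_times) <= 0)) stop("beat times must be strictly increasing")
  if (max(abs(diff(beat_times) * 1000 - rr_ms)) > 1e-6)
    stop("beat_times and rr_ms are inconsistent (tolerance 1e-6 ms)")
  if (is.null(quality_flags)) quality_flags <- rep("ok", n)
  if (length(quality_flags) != n)
    stop("quality_flags must have one entry per interval")
  bad <- setdiff(unique(quality_flags), c("ok", "corrected", "removed-gap"))
  if (length(bad)) stop("unknown quality flag: ", paste(bad, collapse = ", "))
  structure(
    list(beat_times = beat_times, rr_ms = rr_ms,
         quality_flags = quality_flags, record_id = record_id),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf(
    "<rr_series> %s: %d intervals, span %.1f min, mean RR %.0f ms, %d corrected\n",
    ifelse(is.na(x$record_id), "unnamed", x$record_id),
    length(x$rr_ms), diff(range(x$beat_times)) / 60, mean(x$rr_ms),
    sum(x$quality_flags != "ok")))
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$rr_ms)

#' Subject metadata record
#'
#' Holds blood pressure and/or the severity tag for one subject. At least
#' one of `severity` or the pair (`sbp`, `dbp`) must be present; when both
#' pressures are given, `sbp > dbp` is required and a missing severity is
#' derived with [assign_severity()].
#'
#' @param subject_id Identifier.
#' @param sbp,dbp Systolic / diastolic pressure in mmHg (optional).
#' @param severity One of `"mild"`, `"moderate"`, `"severe"` (optional).
#' @return Object of class `subject_record`.
#' @export
subject_record <- function(subject_id, sbp = NA_real_, dbp = NA_real_,
                           severity = NA_character_) {
  has_bp <- is.finite(sbp) && is.finite(dbp)
  if (!has_bp && (is.na(severity) || !nzchar(severity)))
    stop("subject_record needs `severity` or both `sbp` and `dbp`")
  if (has_bp && sbp <= dbp)
    stop("systolic pressure must exceed diastolic pressure")
  if (!is.na(severity) && !severity %in% severity_levels)
    stop("severity must be one of: ", paste(severity_levels, collapse = ", "))
  if (is.na(severity) && has_bp) severity <- assign_severity(sbp, dbp)
  structure(
    list(subject_id = as.character(subject_id), sbp = sbp, dbp = dbp,
         severity = severity),
    class = "subject_record"
  )
}
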