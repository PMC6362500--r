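#' Multiscale segmentation scheme
#'
#' The default seven-level pyramid divides an 8-hour (480 min) record into
#' windows of 480, 240, 120, 60, 30, 20 and 5 minutes, i.e. 1, 2, 4, 8,
#' 16, 24 and 96 segments per level — 151 segments in total.
#'
#' @param levels Window durations in minutes, strictly decreasing; each
#'   must divide `total_duration` exactly.
#' @param total_duration Total analysed duration in minutes (default 480).
#' @param min_beats Minimum number of beats for a segment to be usable
#'   (default 10).
#' @return Object of class `scale_scheme` with elements `levels`,
#'   `total_duration`, `min_beats`, `n_segments` (per level) and `n_total`.
#' @examples
#' s <- scale_scheme()
#' s$n_segments # 1 2 4 8 16 24 96
#' s$n_total    # 151
#' @export
scale_scheme <- function(levels = c(480, 240, 120, 60, 30, 20, 5),
                         total_duration = 480, min_beats = 10L) {
  levels <- as.numeric(levels)
  if (any(diff(levels) >= 0)) stop("level durations must be strictly decreasing")
  if (any(levels <= 0)) stop("level durations must be positive")
  if (any(abs(total_duration / levels - round(total_duration / levels)) > 1e-9))
    stop("every level duration must divide total_duration exactly")
  n_seg <- as.integer(round(total_duration / levels))
  structure(
    list(levels = levels, total_duration = total_duration,
         min_beats = as.integer(min_beats),
         n_segments = n_seg, n_total = sum(n_seg)),
    class = "scale_scheme"
  )
}

#' @export
print.scale_scheme <- function(x, ...) {
  cat(sprintf("<scale_scheme> %d levels over %g min: %s (total %d segments)\n",
              length(x$levels), x$total_duration,
              paste(sprintf("%gmin x%d", x$levels, x$n_segments),
                    collapse = ", "),
              x$n_total))
  invisible(x)
}

#' Segment an RR series at every level of a scale scheme
#'
#' Windows are half-open `[start, end)`: a beat exactly on a boundary
#' belongs to the right-hand window, so every interval onset belongs to
#' exactly one segment per level. Segments with fewer than
#' `scheme$min_beats` interval onsets are marked unusable.
#'
#' @param rr An [rr_series()] spanning (close to) the scheme's total
#'   duration. A shortfall of up to one finest-level window is tolerated
#'   with a message; a series shorter than half the total duration is an
#'   error.
#' @param scheme A [scale_scheme()].
#' @return Named list (one element per level, named by duration in
#'   minutes); each element is a list of segments, each a list with
#'   `level_index`, `start_s`, `end_s`, `rr_ms`, `beat_times` (onsets,
#'   relative to the segment start), `n_beats`, `usable`.
#' @export
segment_rr <- function(rr, scheme = scale_scheme()) {
  stopifnot(inherits(rr, "rr_series"), inherits(scheme, "scale_scheme"))
  total_s <- scheme$total_duration * 60
  span <- rr$beat_times[length(rr$beat_times)] - rr$beat_times[1]
  if (span < total_s / 2)
    stop(sprintf("RR series spans %.1f min, less than half the %g min scheme",
                 span / 60, scheme$total_duration))
  finest_s <- min(scheme$levels) * 60
  if (span < total_s - finest_s)
    stop(sprintf("RR series spans %.1f min; at least %.1f min required",
                 span / 60, (total_s - finest_s) / 60))
  if (span < total_s)
    message(sprintf("RR series %.1f min short of %g min; tail segments may be sparse",
                    (total_s - span) / 60, scheme$total_duration))
  onset <- rr$beat_times[-length(rr$beat_times)] - rr$beat_times[1]
  out <- vector("list", length(scheme$levels))
  names(out) <- as.character(scheme$levels)
  for (li in seq_along(scheme$levels)) {
    dur_s <- scheme$levels[li] * 60
    nseg <- scheme$n_segments[li]
    starts <- (seq_len(nseg) - 1) * dur_s
    bin <- findInterval(onset, c(starts, total_s), rightmost.closed = FALSE)
    segs <- vector("list", nseg)
    for (si in seq_len(nseg)) {
      idx <- which(bin == si)
      segs[[si]] <- list(
        level_index = li, start_s = starts[si], end_s = starts[si] + dur_s,
        rr_ms = rr$rr_ms[idx], beat_times = onset[idx] - starts[si],
        n_beats = length(idx),
        usable = length(idx) >= scheme$min_beats
      )
    }
    out[[li]] <- segs
  }
  out
}

#' Compute the 18 HRV features for every segment of a segmentation
#'
#' @param segments Output of [segment_rr()].
#' @param subject_id Identifier recorded in the output rows.
#' @param ... Passed on to [hrv_features()] (band edges, SampEn and DFA
#'   parameters, ...).
#' @return data.frame with one row per segment: `subject_id`, `level`
#'   (duration, min), `level_index`, `start_s`, `n_beats`, `usable`, then
#'   the 18 feature columns ([hrv_feature_names]). A segment whose feature
#'   vector is incomplete (preconditions of individual features not met) is
#'   marked unusable.
#' @export
segment_features <- function(segments, subject_id = "s1", ...) {
  rows <- list()
  for (li in seq_along(segments)) {
    for (seg in segments[[li]]) {
      fv <- if (seg$usable)
        hrv_features(seg$rr_ms, beat_times = seg$beat_times, ...)
      else
        stats::setNames(rep(NA_real_, length(hrv_feature_names)),
                        hrv_feature_names)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subject_id,
        level = as.numeric(names(segments)[li]),
        level_index = seg$level_index,
        start_s = seg$start_s, n_beats = seg$n_beats,
        usable = seg$usable && all(is.finite(fv)),
        as.list(fv)
      )
    }
  }
  do.call(rbind, rows)
}

#' Assemble per-feature temporal pyramid pools
#'
#' Stacks each feature's values across all usable segments of all levels
#' into one pool per feature, ordered coarsest level first and
#' chronologically within a level. For the default scheme with complete
#' data each pool has 96 + 24 + 16 + 8 + 4 + 2 + 1 = 151 entries; unusable
#' segments are dropped and the realised length recorded.
#'
#' @param features data.frame from [segment_features()].
#' @param scheme The [scale_scheme()] used for segmentation.
#' @return Object of class `hrv_pyramid`: list with `subject_id`, `pools`
#'   (named list of 18 numeric vectors), `n_expected`, `n_realized`,
#'   `scheme`.
#' @export
build_pyramid <- function(features, scheme = scale_scheme()) {
  stopifnot(is.data.frame(features))
  missing_feat <- setdiff(hrv_feature_names, names(features))
  if (length(missing_feat))
    stop("feature table lacks column(s): ", paste(missing_feat, collapse = ", "))
  bad <- features$usable &
    !stats::complete.cases(features[, hrv_feature_names, drop = FALSE])
  if (any(bad)) {
    i <- which(bad)[1]
    nm <- hrv_feature_names[which(!is.finite(as.numeric(
      features[i, hrv_feature_names])))[1]]
    stop(sprintf("usable segment (level %g min, start %g s) is missing feature %s",
                 features$level[i], features$start_s[i], nm))
  }
  ord <- order(features$level_index, features$start_s)
  features <- features[ord, , drop = FALSE]
  keep <- features$usable
  pools <- lapply(hrv_feature_names, function(nm) features[[nm]][keep])
  names(pools) <- hrv_feature_names
  structure(
    list(subject_id = features$subject_id[1], pools = pools,
         n_expected = scheme$n_total, n_realized = sum(keep),
         scheme = scheme),
    class = "hrv_pyramid"
  )
}

#' @export
print.hrv_pyramid <- function(x, ...) {
  cat(sprintf("<hrv_pyramid> %s: %d feature pools of length %d (expected %d)\n",
              x$subject_id, length(x$pools), x$n_realized, x$n_expected))
  invisible(x)
}

#' Single-scale feature pools
#'
#' Restriction of [build_pyramid()] to one level: per feature, the values
#' of all usable segments of that level only (e.g. 16 entries at the
#' 30-minute scale, 24 at 20 minutes).
#'
#' @param features data.frame from [segment_features()].
#' @param level Level duration in minutes; must be one of the levels
#'   present in `features`.
#' @return Named list of 18 numeric vectors.
#' @export
single_scale_pool <- function(features, level) {
  stopifnot(is.data.frame(features))
  if (!level %in% features$level)
    stop("unknown level ", level, " min; available: ",
         paste(sort(unique(features$level), decreasing = TRUE), collapse = ", "))
  sub <- features[features$level == level & features$usable, , drop = FALSE]
  sub <- sub[order(sub$start_s), , drop = FALSE]
  pools <- lapply(hrv_feature_names, function(nm) sub[[nm]])
  names(pools) <- hrv_feature_names
  pools
}
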