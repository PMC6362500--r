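#' Read a raw ECG record
#'
#' Reads a single-lead ECG from either a WFDB record (`.hea` header plus
#' `.dat` signal file, formats 16 and 212) or a CSV file. CSV files may
#' have two columns (time in seconds, voltage in mV) — the sampling rate is
#' then inferred from the time column — or a single voltage column, in
#' which case `fs` must be supplied either as an argument or through a YAML
#' sidecar file `<path>.yaml` containing an `fs:` key.
#'
#' Holter records usually carry several leads; by default the first channel
#' is taken (`channel = 1`).
#'
#' @param path Path to the `.hea` file (or record name without extension)
#'   for WFDB, or to the CSV file.
#' @param format One of `"auto"`, `"wfdb"`, `"csv"`. `"auto"` decides from
#'   the file extension.
#' @param fs Sampling rate in Hz for single-column CSV input.
#' @param channel Which signal channel to extract from a multi-channel
#'   WFDB record (1-based).
#' @return An [ecg_signal()].
#' @export
read_ecg <- function(path, format = c("auto", "wfdb", "csv"), fs = NULL,
                     channel = 1L) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("hea", "dat", "")) "wfdb" else "csv"
  }
  if (format == "wfdb") read_ecg_wfdb(path, channel = channel)
  else read_ecg_csv(path, fs = fs)
}

read_ecg_csv <- function(path, fs = NULL) {
  if (!file.exists(path)) stop("ECG file not found: ", path)
  df <- utils::read.csv(path, header = FALSE,
                        comment.char = "#", strip.white = TRUE)
  first <- suppressWarnings(as.numeric(df[1, 1]))
  if (is.na(first)) { # header row present
    df <- utils::read.csv(path, header = TRUE, comment.char = "#")
  }
  for (j in seq_len(ncol(df))) df[[j]] <- as.numeric(df[[j]])
  if (ncol(df) >= 2L) {
    tm <- df[[1]]
    dt <- diff(tm)
    if (length(dt) < 1L || any(dt <= 0))
      stop("CSV time column must be strictly increasing")
    fs_est <- 1 / stats::median(dt)
    ecg_signal(df[[2]], fs = fs_est,
               record_id = basename(path), t0 = tm[1])
  } else {
    if (is.null(fs)) {
      sidecar <- paste0(path, ".yaml")
      if (file.exists(sidecar)) {
        cfg <- yaml::read_yaml(sidecar)
        fs <- cfg$fs
      }
    }
    if (is.null(fs))
      stop("single-column ECG CSV needs `fs` (argument or ", path,
           ".yaml sidecar)")
    fs <- as.numeric(fs)
    if (!is.finite(fs) || fs <= 0)
      stop("invalid sampling rate fs = ", fs, " (must be > 0)")
    ecg_signal(df[[1]], fs = fs, record_id = basename(path))
  }
}

# Minimal WFDB reader: header line "name nsig fs [nsamp]", one line per
# signal: "file format gain(baseline)/units adcres adczero ...". Supports
# the two formats Holter archives actually use: 16 (little-endian int16)
# and 212 (two 12-bit samples packed into 3 bytes).
read_ecg_wfdb <- function(path, channel = 1L) {
  hea <- if (tolower(tools::file_ext(path)) == "hea") path
         else paste0(sub("\\.dat$", "", path), ".hea")
  if (!file.exists(hea)) stop("WFDB header not found: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("WFDB header is empty: ", hea)
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rec) < 3L)
    stop("WFDB header record line lacks the sampling-rate field")
  record_name <- sub("/.*$", "", rec[1])
  nsig <- suppressWarnings(as.integer(rec[2]))
  fs <- suppressWarnings(as.numeric(sub("/.*$", "", rec[3])))
  if (is.na(nsig) || nsig < 1L)
    stop("WFDB header field `number of signals` is invalid: ", rec[2])
  if (is.na(fs)) stop("WFDB header field `sampling frequency` is garbled: ", rec[3])
  if (fs <= 0) stop("WFDB sampling frequency must be > 0, got ", fs)
  nsamp <- if (length(rec) >= 4L) suppressWarnings(as.integer(rec[4])) else NA
  t0 <- NA
  if (length(rec) >= 5L) { # base time HH:MM:SS
    tparts <- suppressWarnings(as.numeric(strsplit(rec[5], ":")[[1]]))
    if (length(tparts) == 3L && !anyNA(tparts))
      t0 <- tparts[1] * 3600 + tparts[2] * 60 + tparts[3]
  }
  if (length(lines) < 1L + nsig)
    stop("WFDB header declares ", nsig, " signals but lists fewer")
  if (channel < 1L || channel > nsig)
    stop("channel ", channel, " out of range (record has ", nsig, " signals)")
  sig <- strsplit(trimws(lines[1L + channel]), "\\s+")[[1]]
  if (length(sig) < 2L)
    stop("WFDB signal specification line is garbled for channel ", channel)
  dat_file <- file.path(dirname(hea), sig[1])
  fmt <- sub("x.*$|:.*$|\\+.*$", "", sig[2])
  gain <- 200; baseline <- 0
  if (length(sig) >= 3L) {
    gb <- sig[3]
    gain <- suppressWarnings(as.numeric(sub("\\(.*$|/.*$", "", gb)))
    if (is.na(gain) || gain == 0) gain <- 200
    bm <- regmatches(gb, regexec("\\(([-0-9]+)\\)", gb))[[1]]
    if (length(bm) == 2L) baseline <- as.numeric(bm[2])
  }
  if (length(sig) >= 5L) {
    az <- suppressWarnings(as.numeric(sig[5]))
    if (!is.na(az) && length(regmatches(sig[3], regexec("\\(", sig[3]))[[1]]) == 0)
      baseline <- az # adczero stands in when no explicit baseline
  }
  if (!file.exists(dat_file)) stop("WFDB signal file not found: ", dat_file)
  raw <- readBin(dat_file, "raw", n = file.size(dat_file))
  adc <- switch(fmt,
    "16" = {
      v <- readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
                   signed = TRUE, endian = "little")
      matrix(v, nrow = nsig)
    },
    "212" = {
      v <- wfdb_unpack_212(raw)
      matrix(v[seq_len((length(v) %/% nsig) * nsig)], nrow = nsig)
    },
    stop("unsupported WFDB signal format: ", sig[2])
  )
  samples <- (adc[channel, ] - baseline) / gain
  if (!is.na(nsamp) && nsamp > 0 && ncol(adc) >= nsamp)
    samples <- samples[seq_len(nsamp)]
  ecg_signal(samples, fs = fs, record_id = record_name,
             t0 = if (is.na(t0)) NULL else t0)
}

# format 212: bytes b0 b1 b2 encode sample1 = ((b1 & 0x0F) << 8) | b0,
# sample2 = ((b1 & 0xF0) << 4) | b2, each 12-bit two's complement
wfdb_unpack_212 <- function(raw) {
  n3 <- (length(raw) %/% 3L) * 3L
  b <- as.integer(raw[seq_len(n3)])
  b0 <- b[seq(1L, n3, 3L)]; b1 <- b[seq(2L, n3, 3L)]; b2 <- b[seq(3L, n3, 3L)]
  s1 <- bitwAnd(b1, 15L) * 256L + b0
  s2 <- bitwAnd(b1, 240L) * 16L + b2
  v <- as.vector(rbind(s1, s2))
  v[v > 2047L] <- v[v > 2047L] - 4096L
  v
}

#' Read an RR-interval text file
#'
#' Plain text, one RR interval per line, blank lines ignored. Beat times
#' are accumulated from 0 by the cumulative sum of the intervals.
#'
#' @param path File path.
#' @param unit `"ms"` (default) or `"s"`; seconds are converted to ms.
#' @return An [rr_series()].
#' @export
read_rr <- function(path, unit = c("ms", "s")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("RR file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  if (anyNA(vals))
    stop("non-numeric RR value at line ", lineno[which(is.na(vals))[1]],
         " of ", path)
  if (!length(vals)) stop("RR file contains no intervals: ", path)
  if (any(vals <= 0))
    stop("non-positive RR interval at line ", lineno[which(vals <= 0)[1]],
         " of ", path)
  if (unit == "s") vals <- vals * 1000
  rr_series(rr_ms = vals, record_id = basename(path))
}

#' Write an RR series as plain text
#'
#' One interval in ms per line; the format [read_rr()] consumes. Full
#' double precision is kept so a read-back is bitwise identical.
#'
#' @param rr An [rr_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rr <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  writeLines(sprintf("%.17g", rr$rr_ms), path)
  invisible(path)
}

#' Write a feature table to CSV
#'
#' Fixed, documented column order: `subject_id`, `label`, any extra
#' identifier columns (e.g. `level`, `start_s` for per-segment tables),
#' then the 18 HRV features in the order of [hrv_feature_names]. Numeric
#' values are written with 17 significant digits so that
#' [read_feature_table()] round-trips them bitwise.
#'
#' @param rows A data.frame with columns `subject_id`, `label` and all 18
#'   feature columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(rows, path) {
  if (!is.data.frame(rows)) stop("`rows` must be a data.frame")
  need <- c("subject_id", "label")
  missing_id <- setdiff(need, names(rows))
  if (length(missing_id))
    stop("feature table lacks column(s): ", paste(missing_id, collapse = ", "))
  missing_feat <- setdiff(hrv_feature_names, names(rows))
  if (length(missing_feat))
    stop("feature table is ragged: missing feature column(s) ",
         paste(missing_feat, collapse = ", "))
  extras <- setdiff(names(rows), c(need, hrv_feature_names))
  rows <- rows[, c(need, extras, hrv_feature_names), drop = FALSE]
  out <- rows
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return data.frame with `subject_id`, `label` as character, identifier
#'   extras, and numeric feature columns.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in intersect(c(hrv_feature_names, "level", "start_s", "n_beats"),
                       names(df)))
    df[[nm]] <- as.numeric(df[[nm]])
  df
}
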