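# Reading, segmenting and denoising ECG records.
#
# Records come from WFDB header/data pairs (the PhysioNet layout; signed
# 16-bit and 212-packed 12-bit formats are supported) or from the plain
# CSV dialect used throughout the package (first line `fs=<Hz>`, one
# sample per row).  Segmentation cuts fixed-duration, non-overlapping
# windows; denoising removes the coarsest approximation band (baseline
# wander) and soft-thresholds the two finest detail bands
# (high-frequency noise) of an 8-level bior2.6 decomposition.

new_ecg_record <- function(samples, fs, label = "unknown",
                           record_id = "", channel = 1L) {
  if (fs <= 0) stop_invalid("fs must be positive")
  if (length(samples) == 0) stop_invalid("record has no samples")
  structure(
    list(samples = as.numeric(samples), fs = fs, label = label,
         record_id = record_id, channel = as.integer(channel)),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat("<ecg_record>", x$record_id, "| n =", length(x$samples),
      "| fs =", x$fs, "Hz | label =", x$label, "\n")
  invisible(x)
}

new_ecg_segment <- function(samples, fs, label, record_id, start) {
  structure(
    list(samples = as.numeric(samples), fs = fs,
         duration = length(samples) / fs, label = label,
         record_id = record_id, start = as.integer(start)),
    class = "ecg_segment"
  )
}

#' @export
print.ecg_segment <- function(x, ...) {
  cat("<ecg_segment>", x$record_id, "| n =", length(x$samples),
      "| fs =", x$fs, "Hz |", x$duration, "s | label =", x$label, "\n")
  invisible(x)
}

read_ecg_csv <- function(path, label, record_id) {
  lines <- readLines(path, n = 1L)
  if (length(lines) == 0 || !grepl("^fs=", lines[1])) {
    stop_format("CSV must start with an 'fs=<Hz>' header line")
  }
  fs <- suppressWarnings(as.numeric(sub("^fs=", "", lines[1])))
  if (is.na(fs) || fs <= 0) stop_format("invalid sampling rate in CSV header")
  v <- utils::read.csv(path, skip = 1L, header = FALSE)[[1]]
  new_ecg_record(v, fs, label = label, record_id = record_id)
}

read_ecg_wfdb <- function(path, channel, label, record_id) {
  hea_path <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea_path)) stop_format(paste0("missing header ", hea_path))
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rec_name <- hdr[1]
  nsig <- as.integer(hdr[2])
  fs <- if (length(hdr) >= 3) as.numeric(hdr[3]) else 250
  nsamp <- if (length(hdr) >= 4) as.integer(hdr[4]) else NA_integer_
  if (is.na(nsig) || nsig < 1) stop_format("invalid WFDB header")
  if (channel < 1 || channel > nsig) stop_invalid("channel out of range")
  sig <- strsplit(trimws(lines[1 + channel]), "\\s+")[[1]]
  dat_file <- sig[1]
  fmt <- sub("x.*$", "", sig[2])
  gain_field <- if (length(sig) >= 3) sig[3] else "200"
  baseline <- 0
  if (grepl("\\(", gain_field)) {
    baseline <- as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_field))
  }
  gain <- as.numeric(sub("[(/].*$", "", gain_field))
  if (!is.finite(gain) || gain == 0) gain <- 200
  dat_path <- file.path(dirname(hea_path), dat_file)
  if (!file.exists(dat_path)) stop_format(paste0("missing data file ", dat_path))
  raw <- readBin(dat_path, "raw", n = file.info(dat_path)$size)
  adc <- switch(fmt,
    "16" = {
      ints <- readBin(raw, "integer", n = length(raw) %/% 2, size = 2,
                      signed = TRUE, endian = "little")
      matrix(ints, nrow = nsig)[channel, ]
    },
    "212" = {
      if (nsig > 2) stop_format("format 212 supported for <= 2 signals")
      b <- as.integer(raw)
      ntrip <- length(b) %/% 3
      i1 <- 3 * seq_len(ntrip) - 2
      lo1 <- b[i1]
      mid <- b[i1 + 1]
      lo2 <- b[i1 + 2]
      s1 <- lo1 + bitwAnd(mid, 15L) * 256L
      s2 <- lo2 + bitwAnd(mid %/% 16L, 15L) * 256L
      s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
      s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
      if (nsig == 1) s1 else if (channel == 1) s1 else s2
    },
    stop_format(paste0("unsupported WFDB format '", fmt, "'"))
  )
  if (!is.na(nsamp) && length(adc) > nsamp) adc <- adc[seq_len(nsamp)]
  new_ecg_record((adc - baseline) / gain, fs, label = label,
                 record_id = if (nzchar(record_id)) record_id else rec_name,
                 channel = channel)
}

#' Read an ECG record
#'
#' Reads a record from a WFDB header/data pair or from the package CSV
#' dialect. The class label is never guessed from the signal content:
#' it is whatever the caller passes (default `"unknown"`).
#'
#' @param path Path to the `.hea`/record stem (WFDB) or `.csv` file.
#' @param format `"auto"` (by extension), `"wfdb"` or `"csv"`.
#' @param channel 1-based signal index for multichannel WFDB records.
#' @param label Class label to attach: `"NSR"`, `"CHF"` or `"unknown"`.
#' @param record_id Identifier; defaults to the file stem.
#' @return An `ecg_record` with samples in mV and sampling rate in Hz.
#' @export
read_ecg <- function(path, format = c("auto", "wfdb", "csv"), channel = 1L,
                     label = "unknown", record_id = "") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb"
  }
  if (!nzchar(record_id)) {
    record_id <- sub("\\.(csv|hea)$", "", basename(path))
  }
  switch(format,
    csv = read_ecg_csv(path, label, record_id),
    wfdb = read_ecg_wfdb(path, channel, label, record_id)
  )
}

#' Cut a record into fixed-duration segments
#'
#' Produces `floor(N / (t * fs))` consecutive non-overlapping segments
#' of `t` seconds; the trailing remainder is discarded (with a warning
#' when nothing remains).
#'
#' @param record An `ecg_record`.
#' @param t Segment duration in seconds.
#' @return A list of `ecg_segment` objects.
#' @export
segment_record <- function(record, t = 64) {
  stopifnot(inherits(record, "ecg_record"))
  len <- round(t * record$fs)
  n <- length(record$samples)
  if (len < 1) stop_invalid("t * fs must be at least 1 sample")
  k <- n %/% len
  if (k == 0) {
    rlang::warn("record shorter than one segment; returning no segments")
    return(list())
  }
  lapply(seq_len(k), function(i) {
    start <- (i - 1L) * len
    new_ecg_segment(record$samples[(start + 1):(start + len)], record$fs,
                    record$label, record$record_id, start)
  })
}

#' Minimal segmentation time
#'
#' Shortest usable segment duration for a minimum sample count:
#' `n_min / fs` seconds.
#'
#' @param n_min Minimum number of samples (256 for the 8-level
#'   decomposition used in denoising).
#' @param fs Sampling rate in Hz.
#' @return Duration in seconds.
#' @export
minimal_segment_time <- function(n_min = 256, fs) {
  if (!is.numeric(fs) || fs <= 0) stop_invalid("fs must be positive")
  n_min / fs
}

#' Wavelet denoising of an ECG segment
#'
#' 8-level undecimated (`bior2.6`) wavelet decomposition: the
#' coarsest-level smooth is dropped entirely (baseline-wander removal)
#' and the two finest detail bands are soft-thresholded with the
#' universal threshold `sigma * sqrt(2 log N)`, `sigma` estimated from
#' the finest band's median absolute deviation / 0.6745. Output length
#' equals input length.
#'
#' @param segment An `ecg_segment` (or any signal-like object plus
#'   `fs`), longer than 256 samples.
#' @param wavelet Wavelet name (default `"bior2.6"`).
#' @param levels Decomposition depth (default 8).
#' @return The denoised segment (same class as the input where
#'   applicable).
#' @export
denoise <- function(segment, wavelet = "bior2.6", levels = 8L) {
  x <- signal_values(segment)
  n <- length(x)
  if (n <= 256) stop_invalid("denoising requires more than 256 samples")
  m <- modwt(x, wavelet, J = levels)
  sigma <- stats::median(abs(m$W[[1]])) / 0.6745
  thr <- sigma * sqrt(2 * log(n))
  soft <- function(w) sign(w) * pmax(abs(w) - thr, 0)
  m$W[[1]] <- soft(m$W[[1]])
  if (levels >= 2) m$W[[2]] <- soft(m$W[[2]])
  m$V <- numeric(n)   # drop the coarsest smooth: baseline wander
  y <- imodwt(m)
  if (inherits(segment, "ecg_segment")) {
    out <- segment
    out$samples <- y
    out
  } else if (inherits(segment, "mf_signal")) {
    out <- segment
    out$values <- y
    out
  } else {
    y
  }
}
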