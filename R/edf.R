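# Minimal EDF (European Data Format) I/O: fixed-layout ASCII header followed
# by int16 little-endian data records. One data record per second; physical
# unit microvolts. Sufficient for round-tripping the recordings this package
# produces; EDF+ annotations are not supported.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Writes one data record per second; the last record is zero-padded when the
#' recording is not a whole number of seconds. Signals are quantized to the
#' 16-bit digital range against a per-channel symmetric physical range, so a
#' read-back agrees with the original to within one quantization step. The
#' header start date/time is a fixed constant so identical recordings yield
#' byte-identical files.
#'
#' @param recording an [eeg_recording()]; `fs` must be a whole number.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  x <- recording$data
  fs <- recording$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate",
                            call. = FALSE)
  fs <- as.integer(round(fs))
  ns <- nrow(x)
  n_samp <- ncol(x)
  n_rec <- as.integer(ceiling(n_samp / fs))
  if (n_rec * fs > n_samp) {
    x <- cbind(x, matrix(0, ns, n_rec * fs - n_samp))
  }
  # symmetric physical range per channel; at least 1 uV to avoid zero span
  phys_max <- pmax(apply(abs(x), 1L, max), 1)
  phys_max <- ceiling(phys_max * 1000) / 1000
  dig_max <- 32767L
  dig_min <- -32768L

  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8L),
    edf_pad("X X X X", 80L),
    edf_pad(paste("Startdate 01-JAN-2000", recording$reference_name), 80L),
    edf_pad("01.01.00", 8L),
    edf_pad("00.00.00", 8L),
    edf_pad(256L * (1L + ns), 8L),
    edf_pad("", 44L),
    edf_pad(n_rec, 8L),
    edf_pad("1", 8L),
    edf_pad(ns, 4L)
  )
  field <- function(vals, width) {
    paste(vapply(vals, edf_pad, "", width = width), collapse = "")
  }
  hdr <- paste0(
    hdr,
    field(recording$channel_names, 16L),
    field(rep("AgAgCl electrode", ns), 80L),
    field(rep("uV", ns), 8L),
    field(sprintf("%g", -phys_max), 8L),
    field(sprintf("%g", phys_max), 8L),
    field(rep(dig_min, ns), 8L),
    field(rep(dig_max, ns), 8L),
    field(rep("", ns), 80L),
    field(rep(fs, ns), 8L),
    field(rep("", ns), 32L)
  )
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)

  scale <- (dig_max - dig_min) / (2 * phys_max)
  dig <- round((x + phys_max) * scale) + dig_min
  dig <- pmin(pmax(dig, dig_min), dig_max)
  # record-major layout: for each 1-s record, each signal's fs samples
  idx <- matrix(seq_len(n_rec * fs), nrow = fs)
  for (r in seq_len(n_rec)) {
    writeBin(as.integer(t(dig[, idx[, r], drop = FALSE])),
             con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' @param path EDF file path.
#' @return An [eeg_recording()] in microvolts. Channels must share a common
#'   sampling rate.
#' @export
read_edf <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8L); rd(80L)
  rec_id <- rd(80L)
  rd(8L); rd(8L); rd(8L); rd(44L)
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  per <- function(width, n = ns) vapply(seq_len(n), function(i) rd(width), "")
  labels <- per(16L)
  per(80L); per(8L)
  phys_min <- as.numeric(per(8L))
  phys_max <- as.numeric(per(8L))
  dig_min <- as.numeric(per(8L))
  dig_max <- as.numeric(per(8L))
  per(80L)
  spr <- as.integer(per(8L))
  per(32L)
  if (length(unique(spr)) != 1L) {
    stop("EDF reader requires a common sampling rate across signals",
         call. = FALSE)
  }
  fs <- spr[1L] / rec_dur
  raw <- readBin(con, integer(), n = n_rec * sum(spr), size = 2L,
                 endian = "little")
  dat <- matrix(0, ns, n_rec * spr[1L])
  dim(raw) <- c(spr[1L], ns, n_rec)
  for (s in seq_len(ns)) {
    dat[s, ] <- as.numeric(raw[, s, ])
  }
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  dat <- sweep(sweep(dat, 1L, scale, `*`), 1L,
               phys_min - dig_min * scale, `+`)
  ref <- sub("^Startdate \\S+ ?", "", rec_id)
  if (!nzchar(ref)) ref <- "none"
  eeg_recording(dat, fs, labels, ref)
}
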