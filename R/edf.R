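#' EDF input/output
#'
#' Minimal reader/writer for European Data Format (EDF) continuous
#' recordings: 256-byte ASCII header, one 256-byte signal header per channel,
#' then 1-second data records of little-endian 16-bit integers. Physical
#' scaling is chosen per channel to span the signal range, so the round-trip
#' error is bounded by one 16-bit quantization step. The recording is
#' truncated to whole 1-second records on write (the sidecar table of a
#' written study keeps the exact durations).
#'
#' @param recording An `eeg_recording` (sampling rate must be an integer
#'   number of samples per second).
#' @param path File path.
#' @name edf
NULL

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width, flag = " ")
}

# shortest %g representation that fits the fixed-width ASCII field
edf_num <- function(x, width) {
  s <- vapply(x, function(v) {
    for (d in 7:1) {
      out <- sprintf("%.*g", d, v)
      if (nchar(out) <= width) return(out)
    }
    out
  }, "")
  edf_pad(s, width)
}

#' @rdname edf
#' @return `write_edf` invisibly returns `path`.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$sampling_rate
  if (abs(fs - round(fs)) > 1e-9)
    stop("write_edf requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- length(recording$channels)
  n_rec <- ncol(recording$samples) %/% fs
  if (n_rec < 1) stop("recording shorter than one 1-second EDF record")
  X <- recording$samples[, seq_len(n_rec * fs), drop = FALSE]

  pmin <- apply(X, 1, min)
  pmax <- apply(X, 1, max)
  flat <- pmax - pmin < 1e-9
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(edf_pad("0", 8))
  wr(edf_pad(paste0("subject ", recording$subject), 80))
  wr(edf_pad(paste0("condition ", recording$condition), 80))
  wr(edf_pad("01.01.26", 8))
  wr(edf_pad("00.00.00", 8))
  wr(edf_num(256 * (ns + 1), 8))
  wr(edf_pad("", 44))
  wr(edf_num(n_rec, 8))
  wr(edf_num(1, 8))
  wr(edf_num(ns, 4))
  for (ch in recording$channels) wr(edf_pad(ch, 16))
  for (i in seq_len(ns)) wr(edf_pad("AgAgCl electrode", 80))
  for (i in seq_len(ns)) wr(edf_pad("uV", 8))
  for (i in seq_len(ns)) wr(edf_num(pmin[i], 8))
  for (i in seq_len(ns)) wr(edf_num(pmax[i], 8))
  for (i in seq_len(ns)) wr(edf_num(dmin, 8))
  for (i in seq_len(ns)) wr(edf_num(dmax, 8))
  for (i in seq_len(ns)) wr(edf_pad("", 80))
  for (i in seq_len(ns)) wr(edf_num(fs, 8))
  for (i in seq_len(ns)) wr(edf_pad("", 32))

  # reparse the 8-char physical bounds so the scaling matches what a reader sees
  pmin_r <- as.numeric(edf_num(pmin, 8))
  pmax_r <- as.numeric(edf_num(pmax, 8))
  pmin_r <- pmin(pmin_r, pmin)   # keep bounds covering the data
  pmax_r <- pmax(pmax_r, pmax)
  gain <- (dmax - dmin) / (pmax_r - pmin_r)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns)) {
      d <- round((X[i, idx] - pmin_r[i]) * gain[i]) + dmin
      writeBin(as.integer(pmin(pmax(d, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' @rdname edf
#' @param expected_channels Channel labels the file must contain (default the
#'   canonical 32-channel montage); a mismatch is an error naming the
#'   missing/extra channels. Use `NULL` to accept any channel set.
#' @return `read_edf` returns an `eeg_recording`.
#' @export
read_edf <- function(path, expected_channels = eeg_channels()) {
  if (!file.exists(path)) stop("cannot read EDF file: ", path)
  if (file.size(path) < 256) stop("not a valid EDF file (truncated header): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)                                   # version
  patient <- trimws(rd(80))
  rec_id  <- trimws(rd(80))
  rd(8); rd(8)                            # start date/time
  rd(8); rd(44)                           # header bytes, reserved
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1 || is.na(n_rec))
    stop("not a valid EDF file: ", path)
  rdv <- function(w) trimws(vapply(seq_len(ns), function(i) rd(w), ""))
  labels <- rdv(16)
  rdv(80)                                 # transducer
  rdv(8)                                  # dimension
  pmin <- as.numeric(rdv(8))
  pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8))
  dmax <- as.numeric(rdv(8))
  rdv(80)                                 # prefiltering
  spr <- as.integer(rdv(8))
  rdv(32)                                 # reserved

  if (!is.null(expected_channels)) {
    missing_ch <- setdiff(expected_channels, labels)
    extra_ch <- setdiff(labels, expected_channels)
    if (length(missing_ch) || length(extra_ch))
      stop("EDF channel mismatch",
           if (length(missing_ch)) paste0("; missing: ",
                                          paste(missing_ch, collapse = ", ")),
           if (length(extra_ch)) paste0("; unexpected: ",
                                        paste(extra_ch, collapse = ", ")))
  }
  if (length(unique(spr)) != 1)
    stop("read_edf supports a single sampling rate across channels")
  fs <- spr[1] / rec_dur
  total <- n_rec * sum(spr)
  raw <- readBin(con, integer(), n = total, size = 2, endian = "little",
                 signed = TRUE)
  if (length(raw) < total) stop("EDF data section truncated: ", path)
  X <- matrix(0, ns, n_rec * spr[1])
  gain <- (pmax - pmin) / (dmax - dmin)
  ptr <- 0
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      v <- raw[(ptr + 1):(ptr + spr[i])]
      X[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <-
        (v - dmin[i]) * gain[i] + pmin[i]
      ptr <- ptr + spr[i]
    }
  }
  subject <- sub("^subject ", "", patient)
  condition <- sub("^condition ", "", rec_id)
  recording(X, fs, labels, subject = subject, condition = condition)
}
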