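#' Construct a multichannel EEG recording
#'
#' The container passed through every stage of the pipeline: a channel-by-time
#' matrix of potentials in microvolts, with the montage and condition/subject
#' labels attached.
#'
#' @param samples Numeric matrix, channels x time, in microvolts.
#' @param sampling_rate Sampling rate in Hz.
#' @param channels Character vector of channel labels (defaults to rownames of
#'   `samples`, or the canonical 32-channel montage order).
#' @param subject Subject identifier.
#' @param condition Condition label (`"rest"`, `"planned"` or `"unplanned"`,
#'   or any user label).
#' @param montage Matrix of 3D unit-sphere positions, one row per channel;
#'   defaults to the rows of [eeg_montage()] matching `channels`.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(samples, sampling_rate, channels = NULL,
                      subject = NA, condition = NA, montage = NULL) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1)
  if (is.null(channels)) {
    channels <- rownames(samples)
    if (is.null(channels)) {
      std <- eeg_channels()
      if (nrow(samples) != length(std))
        stop("channels must be given when samples do not cover the 32-channel montage")
      channels <- std
    }
  }
  if (length(channels) != nrow(samples))
    stop("length(channels) must equal nrow(samples)")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be positive")
  if (anyNA(samples)) stop("samples contain missing values")
  if (is.null(montage)) {
    std <- eeg_montage()
    montage <- std[intersect(channels, rownames(std)), , drop = FALSE]
    if (!all(channels %in% rownames(std))) {
      # non-standard labels are allowed, but carry no positions
      montage <- std[channels[channels %in% rownames(std)], , drop = FALSE]
    }
  }
  rownames(samples) <- channels
  structure(list(channels = channels, samples = samples,
                 sampling_rate = sampling_rate, subject = subject,
                 condition = condition, montage = montage),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate,
              ncol(x$samples) / x$sampling_rate))
  cat(sprintf("  subject: %s  condition: %s\n", x$subject, x$condition))
  invisible(x)
}

rec_duration <- function(recording) ncol(recording$samples) / recording$sampling_rate

#' Cut a recording into fixed-length epochs
#'
#' Segments the continuous recording into consecutive non-overlapping epochs
#' of `length` seconds; a trailing partial segment is discarded.
#'
#' @param recording An `eeg_recording`.
#' @param length Epoch length in seconds (default 5).
#' @return An `eeg_epochs` object holding an epoch x channel x time array and
#'   the inherited subject/condition labels.
#' @export
#' @examples
#' r <- recording(matrix(rnorm(2 * 1000), 2), 100, channels = c("Fz", "Pz"))
#' e <- make_epochs(r, 5)       # 10 s at 5 s -> 2 epochs
#' dim(e$data)
make_epochs <- function(recording, length = 5) {
  stopifnot(inherits(recording, "eeg_recording"))
  n_samp <- round(length * recording$sampling_rate)
  n_total <- ncol(recording$samples)
  n_epoch <- n_total %/% n_samp
  if (n_epoch < 1)
    stop(sprintf("recording duration (%.2f s) is shorter than the epoch length (%g s)",
                 rec_duration(recording), length))
  dat <- array(0, dim = c(n_epoch, nrow(recording$samples), n_samp),
               dimnames = list(NULL, recording$channels, NULL))
  for (i in seq_len(n_epoch)) {
    idx <- ((i - 1) * n_samp + 1):(i * n_samp)
    dat[i, , ] <- recording$samples[, idx]
  }
  structure(list(data = dat, channels = recording$channels,
                 sampling_rate = recording$sampling_rate,
                 epoch_length = length, subject = recording$subject,
                 condition = recording$condition,
                 montage = recording$montage),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d epochs x %d channels x %d samples (%g s @ %g Hz)\n",
              d[1], d[2], d[3], x$epoch_length, x$sampling_rate))
  cat(sprintf("  subject: %s  condition: %s\n", x$subject, x$condition))
  invisible(x)
}
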