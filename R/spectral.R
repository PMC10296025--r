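#' Band specification
#'
#' Frequency bands are half-open intervals `[f_low, f_high)`, so the 8 Hz bin
#' belongs to alpha (8-13 Hz), not to theta (4-8 Hz).
#'
#' @param name Band name.
#' @param f_low,f_high Band edges in Hz, `f_low < f_high`.
#' @return A `band_spec` list.
#' @export
#' @examples
#' theta <- band_spec("theta", 4, 8)
#' alpha <- band_spec("alpha", 8, 13)
band_spec <- function(name, f_low, f_high) {
  stopifnot(f_low < f_high)
  structure(list(name = name, f_low = f_low, f_high = f_high),
            class = "band_spec")
}

hamming_win <- function(n) 0.54 - 0.46 * cos(2 * pi * seq_len(n) / (n + 1))

# Welch PSD of one vector: Hamming-tapered overlapping segments, averaged
# one-sided periodograms, scaled so sum(power) * df ~ var(x) (Parseval).
welch_vector <- function(x, fs, window = 256, overlap = 0.5) {
  n <- length(x)
  window <- as.integer(window)
  if (window > n) stop("Welch window longer than the signal")
  step <- max(1, round(window * (1 - overlap)))
  starts <- seq(1, n - window + 1, by = step)
  w <- hamming_win(window)
  scale <- 1 / (fs * sum(w^2))
  nb <- window %/% 2 + 1
  acc <- numeric(nb)
  for (s in starts) {
    seg <- x[s:(s + window - 1)] * w
    p <- Mod(stats::fft(seg)[seq_len(nb)])^2 * scale
    acc <- acc + p
  }
  p <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when window is even)
  dbl <- rep(2, nb); dbl[1] <- 1
  if (window %% 2 == 0) dbl[nb] <- 1
  list(frequencies = (seq_len(nb) - 1) * fs / window, power = p * dbl,
       n_segments = length(starts))
}

#' Welch power spectral density of an epoch set
#'
#' Averaged-periodogram PSD per epoch and channel: Hamming-tapered segments
#' of `window` samples with fractional `overlap`, one-sided scaling such that
#' summing power times the bin width over the grid approximates the signal
#' variance.
#'
#' @param epochs An `eeg_epochs`.
#' @param window Segment length in samples (default 256, i.e. 512 ms at
#'   500 Hz).
#' @param overlap Fractional overlap between segments in `[0, 1)`.
#' @return An `eeg_psd` object: `frequencies` (Hz grid up to Nyquist),
#'   `power` (epoch x channel x frequency, uV^2/Hz), plus estimator
#'   metadata and the inherited labels.
#' @export
welch_psd <- function(epochs, window = 256, overlap = 0.5) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (!(overlap >= 0 && overlap < 1)) stop("overlap must be in [0, 1)")
  d <- dim(epochs$data)
  if (window > d[3]) stop("Welch window longer than the epoch")
  fs <- epochs$sampling_rate
  nb <- as.integer(window) %/% 2 + 1
  pow <- array(0, dim = c(d[1], d[2], nb),
               dimnames = list(NULL, epochs$channels, NULL))
  freqs <- NULL
  for (e in seq_len(d[1])) for (ch in seq_len(d[2])) {
    ps <- welch_vector(epochs$data[e, ch, ], fs, window, overlap)
    pow[e, ch, ] <- ps$power
    freqs <- ps$frequencies
  }
  structure(list(frequencies = freqs, power = pow, window = window,
                 overlap = overlap, sampling_rate = fs,
                 channels = epochs$channels, subject = epochs$subject,
                 condition = epochs$condition),
            class = "eeg_psd")
}

#' Mean band power per epoch and channel
#'
#' Averages PSD values over the frequency bins falling in the half-open band
#' `[f_low, f_high)`.
#'
#' @param psd An `eeg_psd`.
#' @param band A [band_spec()] (or numeric length-2 `(f_low, f_high)`).
#' @return Numeric matrix, epochs x channels.
#' @export
band_power <- function(psd, band) {
  stopifnot(inherits(psd, "eeg_psd"))
  if (is.numeric(band) && length(band) == 2)
    band <- band_spec(paste0(band[1], "-", band[2]), band[1], band[2])
  sel <- psd$frequencies >= band$f_low & psd$frequencies < band$f_high
  if (!any(sel))
    stop(sprintf("no frequency bins in band [%g, %g) Hz", band$f_low,
                 band$f_high))
  out <- apply(psd$power[, , sel, drop = FALSE], c(1, 2), mean)
  out <- matrix(out, dim(psd$power)[1], dim(psd$power)[2],
                dimnames = list(NULL, psd$channels))
  out
}

#' Regional condition summary of band power
#'
#' For every condition, averages the per-epoch, per-channel band powers over
#' epochs first, then over the channels of each region, yielding one value
#' per condition and region.
#'
#' @param band_powers Named list, condition label -> epochs x channels matrix
#'   as returned by [band_power()].
#' @param region_map Named list of channel vectors (default [eeg_regions()]).
#' @return Data frame with columns `condition`, `region`, `power`.
#' @export
condition_band_power <- function(band_powers, region_map = eeg_regions()) {
  stopifnot(is.list(band_powers), !is.null(names(band_powers)))
  out <- list()
  for (cond in names(band_powers)) {
    bp <- band_powers[[cond]]
    ch_mean <- colMeans(bp)                       # epochs first
    for (rg in names(region_map)) {
      chans <- region_map[[rg]]
      missing_ch <- setdiff(chans, colnames(bp))
      if (length(missing_ch) > 0)
        stop("region ", rg, " references absent channel(s): ",
             paste(missing_ch, collapse = ", "))
      out[[length(out) + 1]] <- data.frame(
        condition = cond, region = rg,
        power = mean(ch_mean[chans]))
    }
  }
  do.call(rbind, out)
}

#' Normalize a condition value by the resting baseline
#'
#' Plain ratio convention: `condition / rest`. A log-ratio is available via
#' `log = TRUE`.
#'
#' @param condition_value,rest_value Numeric (vectorised); `rest_value` must
#'   be positive.
#' @param log Return `log(condition/rest)` instead of the ratio.
#' @return Normalized value(s).
#' @export
normalize_by_rest <- function(condition_value, rest_value, log = FALSE) {
  if (any(rest_value <= 0))
    stop("rest_value must be positive for rest normalization")
  r <- condition_value / rest_value
  if (log) base::log(r) else r
}
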