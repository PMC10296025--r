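#' Zero-phase FIR band-pass filter
#'
#' Hamming-windowed linear-phase sinc FIR applied with group-delay
#' compensation (symmetric kernel, FFT convolution, odd reflection padding
#' at the edges), so no condition-differential phase lag is introduced. The
#' filter order is derived from the transition bandwidth: by default the
#' transition width equals the low cutoff, which places the stop-band (about
#' 53 dB down for a Hamming design) one octave below the band edge. With the
#' default 0.1 Hz edge this yields a long kernel, which is why convolution
#' is done in the frequency domain. For signals shorter than the kernel, the
#' order is reduced to fit.
#'
#' @param recording An `eeg_recording`.
#' @param low,high Band edges in Hz, `0 < low < high < sampling_rate/2`.
#' @param transition Transition bandwidth in Hz (default `min(low, nyq - high)`).
#' @return The filtered recording.
#' @export
bandpass_filter <- function(recording, low = 0.1, high = 100,
                            transition = NULL) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$sampling_rate
  nyq <- fs / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("band edges must satisfy 0 < low < high < sampling_rate/2")
  if (is.null(transition)) transition <- min(low, nyq - high)
  n <- ncol(recording$samples)
  order <- ceiling(3.3 * fs / transition)
  order <- order + order %% 2                     # even order, odd length
  order <- min(order, 2 * ((n - 1) %/% 2) * 3)    # cap for very short inputs
  order <- max(order, 16)
  h <- fir_bandpass_kernel(order, low, high, fs)
  recording$samples <- fir_zero_phase(recording$samples, h)
  recording
}

# Hamming-windowed sinc band-pass kernel (odd length order+1, symmetric),
# normalized to unit gain at the band centre
fir_bandpass_kernel <- function(order, low, high, fs) {
  k <- 0:order
  c0 <- order / 2
  w <- 0.54 - 0.46 * cos(2 * pi * k / order)
  msinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))
  h <- (2 * high / fs) * msinc(2 * high / fs * (k - c0)) -
       (2 * low / fs) * msinc(2 * low / fs * (k - c0))
  h <- h * w
  f0 <- (low + high) / 2
  h / sum(h * cos(2 * pi * f0 / fs * (k - c0)))
}

# zero-phase application of a symmetric odd-length FIR kernel, FFT convolution
# with odd-reflection edge padding (as filtfilt pads)
fir_zero_phase <- function(X, h) {
  n <- ncol(X)
  L <- length(h)
  half <- (L - 1) %/% 2
  pad <- max(1, min(half, n - 1))
  np <- n + 2 * pad
  nfft <- stats::nextn(np + L - 1, 2)
  H <- stats::fft(c(h, rep(0, nfft - L)))
  out <- X
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
    y <- Re(stats::fft(stats::fft(c(xp, rep(0, nfft - np))) * H,
                       inverse = TRUE)) / nfft
    out[i, ] <- y[(pad + half + 1):(pad + half + n)]
  }
  out
}

#' Power-line notch filter
#'
#' Second-order Butterworth band-stop (f0 +/- 2 Hz) applied forward-backward
#' ([signal::filtfilt]) for zero phase. Attenuation at the line frequency is
#' essentially complete while tones 5 Hz away are passed within 3 dB.
#'
#' @param recording An `eeg_recording`.
#' @param freq Line frequency in Hz (default 50).
#' @param width Half-width of the stop band in Hz (default 2).
#' @return The filtered recording.
#' @export
notch_filter <- function(recording, freq = 50, width = 2) {
  stopifnot(inherits(recording, "eeg_recording"))
  nyq <- recording$sampling_rate / 2
  if (!(freq > 0 && freq < nyq))
    stop("notch frequency must lie in (0, sampling_rate/2)")
  bt <- signal::butter(2, c(freq - width, freq + width) / nyq, type = "stop")
  for (i in seq_len(nrow(recording$samples)))
    recording$samples[i, ] <- signal::filtfilt(bt, recording$samples[i, ])
  recording
}

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the per-sample channel mean of the output is zero.
#'
#' @param recording An `eeg_recording` with at least two channels.
#' @return The re-referenced recording.
#' @export
rereference_average <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (nrow(recording$samples) < 2)
    stop("average reference requires at least 2 channels")
  m <- colMeans(recording$samples)
  recording$samples <- sweep(recording$samples, 2, m)
  recording
}

# symmetric decorrelation: W <- (W W^T)^{-1/2} W
sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), nrow(W)) %*%
    t(e$vectors) %*% W
}

# symmetric fixed-point ICA (tanh contrast) on whitened data
ica_decompose <- function(X, n_components = NULL, max_iter = 64,
                          tol = 1e-4, seed = 1) {
  n <- ncol(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- tcrossprod(Xc) / n
  e <- eigen(C, symmetric = TRUE)
  keep <- which(e$values > 1e-10 * max(e$values))
  if (is.null(n_components)) n_components <- length(keep)
  k <- min(n_components, length(keep))
  if (k < 2) stop("ICA decomposition failed: data rank below 2")
  K <- diag(1 / sqrt(e$values[seq_len(k)]), k) %*% t(e$vectors[, seq_len(k)])
  Z <- K %*% Xc
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  W <- sym_decorrelate(matrix(rnorm(k * k), k))
  for (it in seq_len(max_iter)) {
    G <- tanh(W %*% Z)
    W1 <- sym_decorrelate(G %*% t(Z) / n - diag(rowMeans(1 - G^2), k) %*% W)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  S <- W %*% Z
  A <- Xc %*% t(S) %*% solve(tcrossprod(S))
  list(S = S, A = A, mean = mu, n_components = k, iterations = it)
}

#' Automated independent-component artifact removal
#'
#' Decomposes the recording into independent components (symmetric
#' fixed-point ICA with a tanh contrast after PCA whitening) and removes
#' components matching either artifact phenotype:
#' \describe{
#'   \item{blink proxy}{absolute correlation of the component time course
#'     with the mean of Fp1 and Fp2 above `blink_cor_threshold`;}
#'   \item{rising spectrum}{log-log slope of the component Welch PSD over
#'     5-45 Hz above `slope_threshold` (power increasing with frequency,
#'     the signature of muscle/broadband noise components). The small
#'     positive margin keeps flat-spectrum components, whose estimated slope
#'     fluctuates around zero, from being flagged.}
#' }
#'
#' @param recording An `eeg_recording` of at least `min_duration` seconds.
#' @param n_components Number of components (default: data rank).
#' @param blink_cor_threshold Correlation threshold for the blink criterion.
#' @param slope_threshold Log-log PSD slope threshold.
#' @param min_duration Minimum duration in seconds for a stable decomposition.
#' @param seed Seed of the ICA initialisation.
#' @return List with `recording` (cleaned) and `report` (removed component
#'   indices, the criterion that flagged each, component count, iterations).
#' @export
remove_artifact_components <- function(recording, n_components = NULL,
                                       blink_cor_threshold = 0.8,
                                       slope_threshold = 0.1,
                                       min_duration = 60, seed = 1) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (rec_duration(recording) < min_duration)
    stop(sprintf("recording too short for a stable ICA decomposition (%.1f s < %g s)",
                 rec_duration(recording), min_duration))
  dec <- ica_decompose(recording$samples, n_components, seed = seed)
  k <- dec$n_components
  fs <- recording$sampling_rate

  blink_cor <- rep(NA_real_, k)
  fp <- intersect(c("Fp1", "Fp2"), recording$channels)
  if (length(fp) > 0) {
    ref <- colMeans(recording$samples[fp, , drop = FALSE])
    blink_cor <- abs(as.vector(cor(t(dec$S), ref)))
  }
  slopes <- vapply(seq_len(k), function(i) {
    ps <- welch_vector(dec$S[i, ], fs, window = min(256, ncol(dec$S) %/% 4))
    sel <- ps$frequencies >= 5 & ps$frequencies <= 45 & ps$power > 0
    if (sum(sel) < 3) return(NA_real_)
    unname(coef(lm(log(ps$power[sel]) ~ log(ps$frequencies[sel])))[2])
  }, 0)

  is_blink <- !is.na(blink_cor) & blink_cor > blink_cor_threshold
  is_rising <- !is.na(slopes) & slopes > slope_threshold
  removed <- which(is_blink | is_rising)

  if (length(removed) > 0) {
    recording$samples <- recording$samples -
      dec$A[, removed, drop = FALSE] %*% dec$S[removed, , drop = FALSE]
    rownames(recording$samples) <- recording$channels
  }
  report <- list(
    removed = removed,
    criterion = ifelse(is_blink[removed] & is_rising[removed], "both",
                       ifelse(is_blink[removed], "blink", "rising_psd")),
    blink_correlation = blink_cor,
    psd_slope = slopes,
    n_components = k,
    iterations = dec$iterations
  )
  list(recording = recording, report = report)
}

#' Run the full preprocessing chain on one recording
#'
#' Band-pass, notch, independent-component artifact removal (skipped, with a
#' note in the report, for recordings shorter than `min_ica_duration`),
#' common average reference, and segmentation into fixed-length epochs — in
#' that order.
#'
#' @param recording An `eeg_recording`.
#' @param low,high Band-pass edges, Hz.
#' @param notch Notch frequency, Hz (`NA` to skip).
#' @param epoch_length Epoch length, seconds.
#' @param ica Logical, run component rejection.
#' @param min_ica_duration Minimum duration for ICA, seconds.
#' @param ... Passed to [remove_artifact_components()].
#' @return List with `epochs` (an `eeg_epochs`) and `report`.
#' @export
preprocess_recording <- function(recording, low = 0.1, high = 100,
                                 notch = 50, epoch_length = 5, ica = TRUE,
                                 min_ica_duration = 60, ...) {
  rec <- bandpass_filter(recording, low, high)
  if (!is.na(notch)) rec <- notch_filter(rec, notch)
  report <- list(filter = list(low = low, high = high, notch = notch),
                 ica = NULL)
  if (ica && rec_duration(rec) >= min_ica_duration) {
    cleaned <- remove_artifact_components(rec, min_duration = min_ica_duration,
                                          ...)
    rec <- cleaned$recording
    report$ica <- cleaned$report
  } else if (ica) {
    report$ica <- list(skipped = sprintf(
      "recording of %.1f s below the %g s minimum for ICA",
      rec_duration(rec), min_ica_duration))
  }
  rec <- rereference_average(rec)
  list(epochs = make_epochs(rec, epoch_length), report = report)
}
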