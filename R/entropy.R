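#' Normalized spectral entropy of a power spectrum
#'
#' Shannon entropy of the power spectrum normalized to unit sum, divided by
#' `log(N)` so the result lies in `[0, 1]`: 0 when all power sits in a single
#' bin (a fully predictable rhythm), 1 for a perfectly flat spectrum (white,
#' maximally irregular). Zero-power bins contribute nothing
#' (`0 * log(1/0) = 0`), and the normalization makes the value independent
#' of the logarithm base and of overall power scaling.
#'
#' @param psd_values Numeric vector of per-bin power over the analysis range
#'   (at least 2 bins, all `>= 0`, total `> 0`).
#' @return Scalar in `[0, 1]`.
#' @export
#' @examples
#' spectral_entropy(c(0, 1, 0, 0))    # 0: one-bin spectrum
#' spectral_entropy(rep(3.7, 16))     # 1: flat spectrum
spectral_entropy <- function(psd_values) {
  if (length(psd_values) < 2)
    stop("spectral entropy needs at least 2 frequency bins")
  if (any(psd_values < 0)) stop("negative power values")
  tot <- sum(psd_values)
  if (tot <= 0) stop("total power is zero")
  p <- psd_values / tot
  p <- p[p > 0]
  se <- -sum(p * log(p)) / log(length(psd_values))
  if (se == 0) se <- 0   # normalise the sign of a floating-point -0
  se
}

# epoch x channel spectral entropy over [f_range] from a Welch PSD
entropy_matrix <- function(epochs, window = 256, f_range = c(0.5, 32),
                          overlap = 0.5) {
  psd <- welch_psd(epochs, window = window, overlap = overlap)
  sel <- psd$frequencies >= f_range[1] & psd$frequencies <= f_range[2]
  if (sum(sel) < 2)
    stop("fewer than 2 frequency bins in the entropy range")
  d <- dim(psd$power)
  out <- matrix(0, d[1], d[2], dimnames = list(NULL, psd$channels))
  for (e in seq_len(d[1])) for (ch in seq_len(d[2]))
    out[e, ch] <- spectral_entropy(psd$power[e, ch, sel])
  out
}

#' Per-channel spectral entropy table across conditions
#'
#' Computes the Welch PSD per epoch (window of `window` samples), the
#' normalized spectral entropy over `f_range` per epoch and channel, and
#' averages over epochs, for every condition supplied. When both `planned`
#' and `unplanned` conditions are present a `difference` column
#' (unplanned - planned) is added.
#'
#' @param epochs_by_condition Named list, condition label -> `eeg_epochs`.
#' @param window Welch window, samples (default 256).
#' @param f_range Analysis range in Hz (default 0.5-32; bins with
#'   `f_range[1] <= f <= f_range[2]` are used).
#' @return Data frame with a `channel` column, one entropy column per
#'   condition, and `difference` when applicable. Attribute `n_epochs` holds
#'   the epoch count per condition; a condition with a single epoch is
#'   flagged with a `low_confidence` attribute.
#' @export
channel_entropy_table <- function(epochs_by_condition, window = 256,
                                  f_range = c(0.5, 32)) {
  stopifnot(is.list(epochs_by_condition),
            !is.null(names(epochs_by_condition)))
  chans <- NULL
  cols <- list()
  n_epochs <- integer(0)
  for (cond in names(epochs_by_condition)) {
    em <- entropy_matrix(epochs_by_condition[[cond]], window = window,
                         f_range = f_range)
    if (is.null(chans)) chans <- colnames(em)
    cols[[cond]] <- colMeans(em)
    n_epochs[cond] <- nrow(em)
  }
  out <- data.frame(channel = chans)
  for (cond in names(cols)) out[[cond]] <- unname(cols[[cond]])
  if (all(c("planned", "unplanned") %in% names(cols)))
    out$difference <- out$unplanned - out$planned
  attr(out, "n_epochs") <- n_epochs
  if (any(n_epochs < 2)) attr(out, "low_confidence") <- TRUE
  out
}
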