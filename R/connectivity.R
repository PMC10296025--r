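#' Surface-Laplacian current source density
#'
#' Spherical-spline surface Laplacian of the scalp potentials (Perrin-style):
#' a spline of stiffness `m` is fitted through the electrode potentials on
#' the unit sphere with Tikhonov regularization `lambda`, and its Laplacian
#' is evaluated at the electrode sites. The transform is a fixed linear
#' operator in sensor space, precomputed once from the montage and applied
#' to every sample; a spatially uniform potential maps to (numerically)
#' zero. It sharpens focal activity and suppresses the spatially smooth
#' volume-conducted background before connectivity estimation.
#'
#' @param epochs An `eeg_epochs` whose montage covers all channels.
#' @param m Spline stiffness (default 4).
#' @param lambda Regularization (default 1e-5).
#' @param n_terms Number of Legendre terms in the spline kernels (default 50).
#' @return An `eeg_epochs` of current source density (uV/m^2 on the unit
#'   sphere), same shape and labels.
#' @export
current_source_density <- function(epochs, m = 4, lambda = 1e-5,
                                   n_terms = 50) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  pos <- epochs$montage
  if (is.null(pos) || !all(epochs$channels %in% rownames(pos)))
    stop("montage positions missing for channel(s): ",
         paste(setdiff(epochs$channels, rownames(pos)), collapse = ", "))
  pos <- pos[epochs$channels, , drop = FALSE]
  L <- csd_operator(pos, m = m, lambda = lambda, n_terms = n_terms)
  d <- dim(epochs$data)
  for (e in seq_len(d[1]))
    epochs$data[e, , ] <- L %*% epochs$data[e, , ]
  epochs
}

# Legendre-series spline kernels g (potential) and h (Laplacian) evaluated at
# the matrix of inter-electrode cosine angles, and the resulting linear CSD
# operator with the usual sum-to-zero spline constraint folded in.
csd_operator <- function(pos, m = 4, lambda = 1e-5, n_terms = 50) {
  x <- tcrossprod(pos / sqrt(rowSums(pos^2)))
  x <- pmin(pmax(x, -1), 1)
  G <- matrix(0, nrow(x), ncol(x))
  H <- matrix(0, nrow(x), ncol(x))
  Pn_1 <- matrix(1, nrow(x), ncol(x))   # P_0
  Pn <- x                               # P_1
  for (n in seq_len(n_terms)) {
    cn <- (2 * n + 1) / (4 * pi)
    G <- G + cn / (n * (n + 1))^m * Pn
    H <- H + cn / (n * (n + 1))^(m - 1) * Pn
    # recurrence: (n+1) P_{n+1} = (2n+1) x P_n - n P_{n-1}
    Pn_next <- ((2 * n + 1) * x * Pn - n * Pn_1) / (n + 1)
    Pn_1 <- Pn
    Pn <- Pn_next
  }
  nch <- nrow(x)
  Gi <- solve(G + diag(lambda, nch))
  ones <- rep(1, nch)
  Gi1 <- Gi %*% ones
  H %*% (Gi - (Gi1 %*% t(Gi1)) / sum(Gi1))
}

#' Band-averaged spectral coherence matrix
#'
#' Magnitude coherence `|S_XY| / sqrt(S_XX S_YY)` per frequency bin, averaged
#' over the bins of the requested band. Cross-spectra are averaged across all
#' Hamming-tapered Welch windows of all epochs of the condition before the
#' ratio is formed — averaging is what makes the estimator informative: a
#' single-window estimate is identically 1 for every pair and is rejected.
#'
#' @param epochs An `eeg_epochs` (at least two Welch windows in total).
#' @param band A [band_spec()] or numeric `(f_low, f_high)`; default theta
#'   (4-8 Hz).
#' @param fft_points Window length in samples (default 256).
#' @param overlap Fractional window overlap (default 0.5).
#' @return An `eeg_coherency` object: `matrix` (channel x channel, symmetric,
#'   unit diagonal, entries in `[0, 1]`), `band`, `n_windows`, labels.
#' @export
coherency <- function(epochs, band = band_spec("theta", 4, 8),
                      fft_points = 256, overlap = 0.5) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (is.numeric(band) && length(band) == 2)
    band <- band_spec(paste0(band[1], "-", band[2]), band[1], band[2])
  d <- dim(epochs$data)
  fft_points <- as.integer(fft_points)
  if (fft_points > d[3]) stop("fft_points longer than the epoch")
  fs <- epochs$sampling_rate
  freqs <- (seq_len(fft_points %/% 2 + 1) - 1) * fs / fft_points
  sel <- which(freqs >= band$f_low & freqs < band$f_high)
  if (length(sel) == 0)
    stop(sprintf("no frequency bins in band [%g, %g) Hz", band$f_low,
                 band$f_high))
  step <- max(1, round(fft_points * (1 - overlap)))
  starts <- seq(1, d[3] - fft_points + 1, by = step)
  n_windows <- d[1] * length(starts)
  if (n_windows < 2)
    stop("coherence needs at least two Welch windows: a single-window ",
         "estimate is identically 1 for every channel pair")
  w <- hamming_win(fft_points)
  S <- array(0i, dim = c(d[2], d[2], length(sel)))
  for (e in seq_len(d[1])) {
    seg_mat <- epochs$data[e, , ]
    for (s in starts) {
      seg <- seg_mat[, s:(s + fft_points - 1)] * rep(w, each = d[2])
      Xf <- stats::mvfft(t(seg))[sel, , drop = FALSE]   # bins x channels
      for (b in seq_along(sel))
        S[, , b] <- S[, , b] + outer(Xf[b, ], Conj(Xf[b, ]))
    }
  }
  coh <- matrix(0, d[2], d[2])
  for (b in seq_along(sel)) {
    Sb <- S[, , b] / n_windows
    p <- Re(diag(Sb))
    denom <- sqrt(outer(p, p))
    denom[denom == 0] <- NA
    coh <- coh + Mod(Sb) / denom
  }
  coh <- coh / length(sel)
  coh[is.na(coh)] <- 0
  coh <- (coh + t(coh)) / 2
  diag(coh) <- 1
  dimnames(coh) <- list(epochs$channels, epochs$channels)
  structure(list(matrix = coh, band = band, n_windows = n_windows,
                 channels = epochs$channels, subject = epochs$subject,
                 condition = epochs$condition),
            class = "eeg_coherency")
}

#' Region-pair average coherence
#'
#' Mean of the coherence-matrix entries over all cross-region channel pairs
#' for two distinct regions, or over all unordered distinct within-region
#' pairs (self-pairs excluded) when both regions coincide.
#'
#' @param coherency_matrix An `eeg_coherency` (or plain channel x channel
#'   matrix with dimnames).
#' @param pair Character length-2: the two region names.
#' @param region_map Named list of channel vectors (default [eeg_regions()]).
#' @return Scalar mean coherence.
#' @export
region_pair_coherence <- function(coherency_matrix, pair,
                                  region_map = eeg_regions()) {
  M <- if (inherits(coherency_matrix, "eeg_coherency"))
    coherency_matrix$matrix else coherency_matrix
  stopifnot(length(pair) == 2)
  if (!all(pair %in% names(region_map)))
    stop("unknown region(s): ",
         paste(setdiff(pair, names(region_map)), collapse = ", "))
  a <- intersect(region_map[[pair[1]]], rownames(M))
  b <- intersect(region_map[[pair[2]]], rownames(M))
  if (identical(pair[1], pair[2])) {
    if (length(a) < 2) stop("within-region pair needs at least 2 channels")
    vals <- M[a, a][upper.tri(matrix(0, length(a), length(a)))]
  } else {
    if (length(a) == 0 || length(b) == 0)
      stop("empty channel set for region pair ", pair[1], "-", pair[2])
    vals <- as.vector(M[a, b, drop = FALSE])
  }
  mean(vals)
}
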