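# Shared fixtures: reduced-size study configurations keep test runtime low;
# effect sizes, noise levels and rates stay at the package defaults.

small_config <- function(duration = 70, n_subjects = 2, seed = 42, ...) {
  sim_config(n_subjects = n_subjects,
             condition_duration_mean = c(planned = duration,
                                         unplanned = duration),
             condition_duration_sd = c(planned = 0, unplanned = 0),
             seed = seed, ...)
}

# two-channel white-noise recording
noise_recording <- function(n = 5000, fs = 500, sd = 1, seed = 1,
                            channels = c("Fz", "Pz")) {
  set.seed(seed)
  recording(matrix(rnorm(length(channels) * n, 0, sd),
                   length(channels)), fs, channels = channels)
}

# sinusoid recording on given channels
tone_recording <- function(freq, dur = 60, fs = 500, amp = 1,
                           channels = "Fz") {
  tt <- seq_len(dur * fs) / fs
  recording(matrix(rep(amp * sin(2 * pi * freq * tt),
                       length(channels)), length(channels), byrow = TRUE),
            fs, channels = channels)
}

# epochs holding a common narrowband source plus independent noise on two
# channels: the analytic band coherence is Ps / (Ps + Pn)
common_source_epochs <- function(n_sec = 100, fs = 500, src_rms = 2,
                                 noise_sd = 2, band = c(4, 8), seed = 11) {
  set.seed(seed)
  n <- n_sec * fs
  src <- eegattn:::narrowband_noise(n, fs, band, src_rms)
  x <- rbind(src + rnorm(n, 0, noise_sd), src + rnorm(n, 0, noise_sd))
  make_epochs(recording(x, fs, channels = c("Fz", "Pz")), 5)
}

# hand-built PSD container for band_power unit tests
flat_psd <- function(value = 1, n_epochs = 2, channels = c("Fz", "Pz"),
                     fs = 500, window = 256) {
  nb <- window %/% 2 + 1
  structure(list(
    frequencies = (seq_len(nb) - 1) * fs / window,
    power = array(value, dim = c(n_epochs, length(channels), nb),
                  dimnames = list(NULL, channels, NULL)),
    window = window, overlap = 0.5, sampling_rate = fs,
    channels = channels, subject = NA, condition = NA),
    class = "eeg_psd")
}
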