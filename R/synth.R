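#' Specify a planted oscillatory source
#'
#' Oscillators are narrowband Gaussian processes (spectrally shaped white
#' noise), not pure sinusoids, matching the stochastic character of EEG
#' rhythms. A `shared` source is one latent time series projected to all
#' target channels — the vehicle for planting inter-channel coherence — while
#' a non-shared spec draws an independent oscillator per channel, which moves
#' band power without creating coherence.
#'
#' @param band Numeric length-2, `(f_low, f_high)` in Hz, `f_low < f_high`.
#' @param channels Character vector of target channel labels (must belong to
#'   the 32-channel montage).
#' @param amplitude Named numeric vector mapping condition labels to RMS
#'   amplitudes in microvolts (conditions not named get amplitude 0).
#' @param shared Logical; see above.
#' @param name Optional label used in reports.
#' @return A `source_spec` list.
#' @export
source_spec <- function(band, channels, amplitude, shared = FALSE,
                        name = NULL) {
  stopifnot(length(band) == 2, band[1] < band[2], band[1] > 0)
  bad <- setdiff(channels, eeg_channels())
  if (length(bad) > 0)
    stop("unknown channel(s) in source spec: ", paste(bad, collapse = ", "))
  if (any(amplitude < 0)) stop("source amplitudes must be >= 0")
  if (is.null(names(amplitude)) || any(names(amplitude) == ""))
    stop("amplitude must be a named (condition -> uV RMS) vector")
  structure(list(band = as.numeric(band), channels = channels,
                 amplitude = amplitude, shared = isTRUE(shared),
                 name = if (is.null(name)) paste0(band[1], "-", band[2], "Hz")
                        else name),
            class = "source_spec")
}

#' Default planted sources of the simulated shopping study
#'
#' Encodes the condition contrasts the analysis is designed to detect:
#' \itemize{
#'   \item frontal-midline theta (4-8 Hz), independent per channel, elevated
#'     in the planned condition (goal-driven attention);
#'   \item a single shared theta source projected to frontal and parietal
#'     channels, mixed more strongly in the planned condition — this is what
#'     produces elevated frontoparietal coherence;
#'   \item alpha (8-13 Hz) over frontal and parietal channels, suppressed in
#'     the unplanned condition (external sensory intake);
#'   \item a narrow ~10 Hz rhythm at Fp1, F7, Oz and P8 present only in the
#'     planned condition, which concentrates the spectrum there and lowers
#'     spectral entropy relative to the unplanned condition.
#' }
#' Amplitudes are RMS microvolts against a 10 uV RMS 1/f background.
#'
#' @return List of [source_spec()] objects.
#' @export
default_sources <- function() {
  list(
    source_spec(c(4, 8), c("Fz", "FC1", "FC2", "Cz"),
                c(rest = 2, planned = 5, unplanned = 2),
                name = "frontal_midline_theta"),
    source_spec(c(4, 8), c("F3", "Fz", "F4", "P3", "Pz", "P4"),
                c(rest = 1.5, planned = 4, unplanned = 1.5),
                shared = TRUE, name = "frontoparietal_shared_theta"),
    source_spec(c(8, 13),
                c("Fp1", "Fp2", "F3", "F4", "Fz", "F7", "F8",
                  "P3", "P4", "Pz", "P7", "P8"),
                c(rest = 4, planned = 4, unplanned = 1.5),
                name = "frontoparietal_alpha"),
    source_spec(c(9.5, 10.5), c("Fp1", "F7", "Oz", "P8"),
                c(rest = 0, planned = 6, unplanned = 0),
                name = "planned_narrowband")
  )
}

#' Simulation configuration
#'
#' Defaults encode the emulated study: 29 subjects, 500 Hz, 32 channels,
#' 30 s eyes-closed rest, condition durations drawn from truncated normals
#' with means 238.87 s (planned) and 228.00 s (unplanned) and SDs 85.57 and
#' 107.20 s (floor 60 s), a 1/f background, the planted sources of
#' [default_sources()], eye blinks at 12/min, and a 6-item shopping list with
#' on average ~5.9 unplanned purchases per subject.
#'
#' @param n_subjects Number of subjects.
#' @param sampling_rate Hz.
#' @param rest_duration Rest segment length, seconds.
#' @param condition_duration_mean,condition_duration_sd Named numeric vectors
#'   (`planned`, `unplanned`), seconds.
#' @param duration_floor Minimum condition duration, seconds.
#' @param background_exponent 1/f exponent beta of the background PSD
#'   (power ~ f^-beta).
#' @param background_rms Background RMS amplitude, microvolts.
#' @param oscillator_specs List of [source_spec()] objects.
#' @param blink_rate Eye-blink rate, events per minute.
#' @param noise_sd White sensor-noise SD, microvolts.
#' @param list_items Shopping-list length (planned purchases per subject).
#' @param unplanned_rate Poisson mean of unplanned purchases per subject.
#' @param budget_total,budget_list Budget in currency units.
#' @param seed Master seed; all per-recording streams derive from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 29,
                       sampling_rate = 500,
                       rest_duration = 30,
                       condition_duration_mean = c(planned = 238.87,
                                                   unplanned = 228.00),
                       condition_duration_sd = c(planned = 85.57,
                                                 unplanned = 107.20),
                       duration_floor = 60,
                       background_exponent = 1,
                       background_rms = 10,
                       oscillator_specs = default_sources(),
                       blink_rate = 12,
                       noise_sd = 2,
                       list_items = 6,
                       unplanned_rate = 172 / 29,
                       budget_total = 250,
                       budget_list = 120,
                       seed = 42) {
  condition_duration_mean <- unlist(condition_duration_mean)  # YAML maps
  condition_duration_sd <- unlist(condition_duration_sd)
  stopifnot(n_subjects >= 1, sampling_rate > 0, rest_duration > 0,
            all(condition_duration_mean > 0), blink_rate >= 0, noise_sd >= 0,
            background_rms >= 0, list_items >= 0)
  fmax <- max(c(0, vapply(oscillator_specs, function(s) s$band[2], 0)))
  if (sampling_rate <= 2 * fmax)
    stop("sampling_rate must exceed twice the highest oscillator frequency")
  structure(list(n_subjects = n_subjects, sampling_rate = sampling_rate,
                 rest_duration = rest_duration,
                 condition_duration_mean = condition_duration_mean,
                 condition_duration_sd = condition_duration_sd,
                 duration_floor = duration_floor,
                 background_exponent = background_exponent,
                 background_rms = background_rms,
                 oscillator_specs = oscillator_specs,
                 blink_rate = blink_rate, noise_sd = noise_sd,
                 list_items = list_items, unplanned_rate = unplanned_rate,
                 budget_total = budget_total, budget_list = budget_list,
                 seed = as.integer(seed)),
            class = "sim_config")
}

sim_conditions <- function() c("rest", "planned", "unplanned")

# deterministic per-(seed, subject, condition) stream seed, kept below 2^31
derive_seed <- function(seed, subject_id, condition, offset = 0) {
  code <- match(condition, sim_conditions())
  if (is.na(code)) code <- 97L
  as.integer((as.double(seed) * 7919 + subject_id * 104729 +
              code * 15485863 + offset) %% 2147483629)
}

# Gaussian noise with target one-sided spectral shape `shape(f)` (unit-free),
# scaled to the requested RMS. Shaping is done in the frequency domain.
shaped_noise <- function(n, fs, shape, rms) {
  if (rms <= 0 || n < 4) return(numeric(n))
  nf <- (n - 1) %/% 2                  # strictly positive, non-Nyquist bins
  f <- (1:nf) * fs / n
  amp <- shape(f)
  spec <- complex(real = rnorm(nf), imaginary = rnorm(nf)) * amp
  full <- complex(length.out = n)
  full[2:(nf + 1)] <- spec
  full[n + 1 - (1:nf)] <- Conj(spec)
  x <- Re(fft(full, inverse = TRUE)) / n
  s <- sd(x)
  if (s == 0) return(numeric(n))
  (x - mean(x)) * rms / s
}

pink_noise <- function(n, fs, exponent, rms)
  shaped_noise(n, fs, function(f) f^(-exponent / 2), rms)

narrowband_noise <- function(n, fs, band, rms)
  shaped_noise(n, fs, function(f) as.numeric(f >= band[1] & f <= band[2]), rms)

rtruncnorm1 <- function(mean, sd, floor) {
  if (sd <= 0) return(max(mean, floor))
  for (i in 1:1000) {
    d <- rnorm(1, mean, sd)
    if (d >= floor) return(d)
  }
  floor
}

#' Generate one synthetic EEG recording
#'
#' Builds a 32-channel recording for one subject and condition as the sum of
#' a 1/f background, the configured band-limited oscillators (with
#' condition-specific amplitudes), white sensor noise and eye-blink
#' transients. The random stream is derived deterministically from
#' `(config$seed, subject_id, condition)`, so any single recording can be
#' regenerated in isolation, bit-identically.
#'
#' @param config A [sim_config()].
#' @param subject_id Integer subject index (1-based, `<= n_subjects`).
#' @param condition `"rest"`, `"planned"` or `"unplanned"`.
#' @return An `eeg_recording`.
#' @export
generate_recording <- function(config, subject_id, condition) {
  stopifnot(inherits(config, "sim_config"))
  if (!condition %in% sim_conditions())
    stop("unknown condition label: ", condition)
  if (subject_id < 1 || subject_id > config$n_subjects)
    stop("subject_id out of range")
  fs <- config$sampling_rate
  chans <- eeg_channels()

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, subject_id, condition))

  dur <- if (condition == "rest") config$rest_duration else
    rtruncnorm1(config$condition_duration_mean[[condition]],
                config$condition_duration_sd[[condition]],
                config$duration_floor)
  n <- round(dur * fs)

  X <- matrix(0, length(chans), n, dimnames = list(chans, NULL))
  for (ch in seq_along(chans)) {
    if (config$background_rms > 0)
      X[ch, ] <- X[ch, ] + pink_noise(n, fs, config$background_exponent,
                                      config$background_rms)
    if (config$noise_sd > 0)
      X[ch, ] <- X[ch, ] + rnorm(n, 0, config$noise_sd)
  }
  for (spec in config$oscillator_specs) {
    amp <- spec$amplitude[condition]
    amp <- if (is.na(amp)) 0 else unname(amp)
    if (amp <= 0) next
    if (spec$shared) {
      latent <- narrowband_noise(n, fs, spec$band, 1)
      for (ch in spec$channels) X[ch, ] <- X[ch, ] + amp * latent
    } else {
      for (ch in spec$channels)
        X[ch, ] <- X[ch, ] + narrowband_noise(n, fs, spec$band, amp)
    }
  }
  rec <- recording(X, fs, chans, subject = subject_id, condition = condition)
  if (config$blink_rate > 0)
    rec <- inject_blinks(rec, config$blink_rate,
                         seed = derive_seed(config$seed, subject_id,
                                            condition, offset = 1),
                         amplitude = 10 * max(config$background_rms, 1))
  rec
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Add stereotyped eye-blink artifacts to a recording
#'
#' Blinks are 400 ms raised-cosine transients with a frontally dominated
#' spatial profile (maximal at Fp1/Fp2, decaying toward posterior channels,
#' weight proportional to the squared positive anterior coordinate of the
#' montage). Event count is Poisson with the requested rate; `rate = 0`
#' returns the input unchanged.
#'
#' @param recording An `eeg_recording`.
#' @param rate Events per minute (>= 0).
#' @param seed Optional integer seed for the blink stream.
#' @param amplitude Peak amplitude at the frontopolar channels, microvolts.
#' @return The recording with blinks added.
#' @export
inject_blinks <- function(recording, rate, seed = NULL, amplitude = 100) {
  stopifnot(inherits(recording, "eeg_recording"), rate >= 0)
  if (rate == 0) return(recording)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  fs <- recording$sampling_rate
  n <- ncol(recording$samples)
  dur <- n / fs
  blink_len <- round(0.4 * fs)
  n_events <- rpois(1, rate * dur / 60)
  if (n_events == 0 || n <= blink_len) return(recording)
  template <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = blink_len)))
  w <- numeric(length(recording$channels))
  pos <- recording$montage
  idx <- match(rownames(pos), recording$channels)
  w[idx] <- pmax(pos[, "y"], 0)^2
  if (max(w) > 0) w <- w / max(w)
  onsets <- sort(sample.int(n - blink_len, n_events, replace = TRUE))
  for (t0 in onsets) {
    span <- t0:(t0 + blink_len - 1)
    recording$samples[, span] <- recording$samples[, span] +
      amplitude * outer(w, template)
  }
  recording
}

#' Behavioral purchase log of the simulated study
#'
#' Every completing subject buys exactly the `list_items` products of the
#' shopping list (planned purchases), then a Poisson-distributed number of
#' unplanned purchases from the remaining budget.
#'
#' @param config A [sim_config()].
#' @return Data frame with one row per subject: `subject`, `list_items`,
#'   `planned_purchases`, `unplanned_purchases`, `budget_total`,
#'   `budget_list`.
#' @export
behavioral_log <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, 0, "rest", offset = 2))
  data.frame(
    subject = seq_len(config$n_subjects),
    list_items = config$list_items,
    planned_purchases = config$list_items,
    unplanned_purchases = rpois(config$n_subjects, config$unplanned_rate),
    budget_total = config$budget_total,
    budget_list = config$budget_list
  )
}

#' Generate a full synthetic study
#'
#' One rest, one planned and one unplanned recording per subject, plus the
#' behavioral purchase log and a sidecar table of recording metadata.
#'
#' @param config A [sim_config()].
#' @return List with elements `recordings` (list of `eeg_recording`, in
#'   subject-major order), `behavioral` (see [behavioral_log()]) and
#'   `sidecar` (data frame: subject, condition, duration, seed).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  recs <- list()
  side <- list()
  k <- 0
  for (s in seq_len(config$n_subjects)) {
    for (cond in sim_conditions()) {
      k <- k + 1
      rec <- generate_recording(config, s, cond)
      recs[[k]] <- rec
      side[[k]] <- data.frame(subject = s, condition = cond,
                              duration = rec_duration(rec),
                              seed = derive_seed(config$seed, s, cond))
    }
  }
  list(recordings = recs, behavioral = behavioral_log(config),
       sidecar = do.call(rbind, side))
}

#' Write a generated study to disk
#'
#' One EDF file per subject x condition plus CSV sidecar and behavioral
#' tables.
#'
#' @param study Result of [generate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of EDF paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (rec in study$recordings) {
    p <- file.path(dir, sprintf("sub-%02d_%s.edf", as.integer(rec$subject),
                                rec$condition))
    write_edf(rec, p)
    paths <- c(paths, p)
  }
  write.csv(study$sidecar, file.path(dir, "recordings.csv"),
            row.names = FALSE)
  write.csv(study$behavioral, file.path(dir, "behavioral.csv"),
            row.names = FALSE)
  invisible(paths)
}
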