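test_that("degenerate config with all amplitudes zero yields silent channels", {
  cfg <- small_config(n_subjects = 1, background_rms = 0, noise_sd = 0,
                      blink_rate = 0, oscillator_specs = list())
  r <- generate_recording(cfg, 1, "planned")
  expect_equal(max(abs(r$samples)), 0)
  expect_identical(r$channels, eegattn:::eeg_channels())
})

test_that("the same seed regenerates a recording bit-identically", {
  cfg <- small_config(duration = 62)
  r1 <- generate_recording(cfg, 1, "unplanned")
  r2 <- generate_recording(cfg, 1, "unplanned")
  expect_identical(r1$samples, r2$samples)
  # different subject or condition gives a different stream
  expect_false(identical(
    generate_recording(cfg, 2, "unplanned")$samples[1, 1:100],
    r1$samples[1, 1:100]))
})

test_that("invalid condition labels and source channels are rejected", {
  cfg <- small_config(n_subjects = 1)
  expect_error(generate_recording(cfg, 1, "browsing"), "condition")
  expect_error(source_spec(c(4, 8), c("Fz", "XX9"), c(planned = 1)), "XX9")
  expect_error(source_spec(c(8, 4), "Fz", c(planned = 1)))
  expect_error(sim_config(oscillator_specs = list(
    source_spec(c(200, 260), "Fz", c(planned = 1)))), "sampling_rate")
})

test_that("shared-source theta coherence grows with source-to-noise ratio and matches the closed form", {
  # one shared 6 Hz source on Fz and Pz against independent white noise:
  # analytic band coherence in the long-signal limit is Ps / (Ps + Pn)
  noise_sd <- 2
  src_band <- c(3.5, 8.5)            # covers every [4,8) analysis bin
  coh_at <- function(amp) {
    cfg <- small_config(duration = 120, n_subjects = 1, background_rms = 0,
                        noise_sd = noise_sd, blink_rate = 0,
                        oscillator_specs = list(
                          source_spec(src_band, c("Fz", "Pz"),
                                      c(planned = amp), shared = TRUE)))
    ep <- make_epochs(generate_recording(cfg, 1, "planned"), 5)
    coherency(ep, band_spec("theta", 4, 8))$matrix["Fz", "Pz"]
  }
  amps <- c(0.1, 0.2, 0.4, 0.8)
  cohs <- vapply(amps, coh_at, 0)
  expect_true(all(diff(cohs) > 0))
  # Ps/(Ps+Pn): flat source density amp^2 / bandwidth vs white noise density
  ps <- amps^2 / diff(src_band)
  pn <- noise_sd^2 / 250
  expect_equal(cohs, ps / (ps + pn), tolerance = 0.05)
})

test_that("a generated study has three recordings per subject and a consistent behavioral log", {
  cfg <- small_config(n_subjects = 1, duration = 61)
  st <- generate_study(cfg)
  expect_length(st$recordings, 3)
  expect_setequal(st$sidecar$condition, c("rest", "planned", "unplanned"))
  expect_equal(st$behavioral$planned_purchases, cfg$list_items)
  # behavioral invariant at any size: planned total = n_subjects x list_items
  bl <- behavioral_log(sim_config(n_subjects = 12, seed = 3))
  expect_equal(sum(bl$planned_purchases), 12 * 6)
})

test_that("blink injection is a no-op at rate 0, Poisson-distributed, and frontally dominated", {
  r0 <- noise_recording(n = 30000, channels = c("Fp1", "Fz", "O1"))
  expect_identical(inject_blinks(r0, 0), r0)
  # expected count: 12/min over 60 s -> mean 12
  counts <- vapply(1:40, function(s) {
    ri <- inject_blinks(noise_recording(n = 30000, sd = 0.001, seed = s,
                                        channels = c("Fp1", "O1")),
                        rate = 12, seed = s, amplitude = 50)
    # count events from the Fp1 trace: blink peaks are ~50 against ~0 noise
    sum(diff(ri$samples["Fp1", ] > 25) == 1)
  }, 0)
  # threshold-crossing counting merges the occasional overlapping pair, so
  # allow a band around the nominal Poisson mean of 12
  expect_gt(mean(counts), 10.5)
  expect_lt(mean(counts), 13.5)
  expect_gt(var(counts), 0)          # stochastic, not fixed
  rb <- inject_blinks(noise_recording(n = 30000,
                                      channels = c("Fp1", "O1")),
                      rate = 20, seed = 1, amplitude = 100)
  expect_gt(var(rb$samples["Fp1", ]), var(rb$samples["O1", ]))
})

test_that("background spectral slope recovers the configured 1/f exponent", {
  for (beta in c(1, 1.5)) {
    cfg <- small_config(duration = 180, n_subjects = 1, noise_sd = 0,
                        blink_rate = 0, oscillator_specs = list(),
                        background_exponent = beta)
    r <- generate_recording(cfg, 1, "planned")
    pw <- welch_psd(make_epochs(r, 5), window = 1024)
    sel <- pw$frequencies >= 1 & pw$frequencies <= 40
    mp <- apply(pw$power[, 1, sel], 2, mean)
    slope <- unname(coef(lm(log(mp) ~ log(pw$frequencies[sel])))[2])
    expect_equal(slope, -beta, tolerance = 0.2)
  }
})
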