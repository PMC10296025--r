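test_that("Welch PSD satisfies Parseval and recovers sinusoid power", {
  expect_equal(max(welch_psd(make_epochs(
    recording(matrix(0, 1, 5000), 500, channels = "Fz"), 10))$power), 0)

  r <- noise_recording(n = 50000, sd = 1, seed = 3, channels = "Fz")
  pw <- welch_psd(make_epochs(r, 100))
  df <- pw$frequencies[2] - pw$frequencies[1]
  expect_equal(sum(pw$power[1, 1, ]) * df, 1, tolerance = 0.05)

  # amplitude A at a bin-centred frequency -> integrated power A^2/2
  A <- 3; f0 <- 10 * 500 / 256
  tone <- tone_recording(f0, dur = 100, amp = A)
  pt <- welch_psd(make_epochs(tone, 100))
  expect_equal(sum(pt$power[1, 1, ]) * df, A^2 / 2, tolerance = 0.05)

  expect_error(welch_psd(make_epochs(noise_recording(n = 500), 0.4)),
               "window")
  expect_error(welch_psd(make_epochs(noise_recording(n = 5000), 5),
                         overlap = 1))
})

test_that("band power averages PSD bins over a half-open band", {
  fp <- flat_psd(value = 2.5)
  expect_equal(unname(band_power(fp, band_spec("theta", 4, 8))),
               matrix(2.5, 2, 2))
  expect_equal(unname(band_power(fp, band_spec("alpha", 8, 13))),
               matrix(2.5, 2, 2))
  # power entirely outside the band reads as zero
  zp <- flat_psd(value = 0)
  zp$power[, , zp$frequencies >= 20] <- 7
  expect_equal(unname(band_power(zp, band_spec("theta", 4, 8))),
               matrix(0, 2, 2))
  # the 8 Hz boundary belongs to alpha, not theta (grid with an exact 8 Hz bin)
  bp <- flat_psd(value = 0, fs = 512)
  k8 <- which(bp$frequencies == 8)
  bp$power[, , k8] <- 1
  expect_equal(sum(band_power(bp, band_spec("theta", 4, 8))), 0)
  expect_gt(sum(band_power(bp, band_spec("alpha", 8, 13))), 0)
  expect_error(band_power(fp, band_spec("narrow", 5.0, 5.01)), "bins")
})

test_that("a 6 Hz narrowband signal shows theta far above alpha", {
  cfg <- small_config(n_subjects = 1, duration = 70, background_rms = 0,
                      noise_sd = 0.5, blink_rate = 0,
                      oscillator_specs = list(
                        source_spec(c(5.5, 6.5), "Fz", c(planned = 5))))
  psd <- welch_psd(make_epochs(generate_recording(cfg, 1, "planned"), 5))
  th <- mean(band_power(psd, band_spec("theta", 4, 8))[, "Fz"])
  al <- mean(band_power(psd, band_spec("alpha", 8, 13))[, "Fz"])
  expect_gt(th, 10 * al)
})

test_that("band power is invariant to epoch and channel reordering and bounded by band extremes", {
  r <- noise_recording(n = 20000, channels = c("Fz", "Cz", "Pz"), seed = 6)
  psd <- welch_psd(make_epochs(r, 5))
  bp <- band_power(psd, band_spec("theta", 4, 8))
  perm_e <- sample(nrow(bp)); perm_c <- c(3, 1, 2)
  psd2 <- psd
  psd2$power <- psd$power[perm_e, perm_c, , drop = FALSE]
  psd2$channels <- psd$channels[perm_c]
  dimnames(psd2$power)[[2]] <- psd2$channels
  bp2 <- band_power(psd2, band_spec("theta", 4, 8))
  expect_equal(bp2, bp[perm_e, perm_c])
  sel <- psd$frequencies >= 4 & psd$frequencies < 8
  expect_true(all(bp <= apply(psd$power[, , sel], c(1, 2), max) + 1e-12))
  expect_true(all(bp >= apply(psd$power[, , sel], c(1, 2), min) - 1e-12))
})

test_that("condition summaries average epochs first, then region channels", {
  set.seed(4)
  bp <- matrix(rnorm(20, 10), 5, 4,
               dimnames = list(NULL, c("Fz", "F3", "Pz", "P3")))
  rm <- list(FzOnly = "Fz", Pair = c("Pz", "P3"))
  out <- condition_band_power(list(planned = bp), rm)
  expect_equal(out$power[out$region == "FzOnly"], mean(bp[, "Fz"]))
  expect_equal(out$power[out$region == "Pair"],
               mean(colMeans(bp[, c("Pz", "P3")])))
  # epoch order cannot matter
  out2 <- condition_band_power(list(planned = bp[5:1, ]), rm)
  expect_equal(out2, out)
  # region averages stay within member-channel bounds
  cm <- colMeans(bp[, c("Pz", "P3")])
  expect_gte(out$power[out$region == "Pair"], min(cm))
  expect_lte(out$power[out$region == "Pair"], max(cm))
  expect_error(condition_band_power(list(planned = bp),
                                    list(Bad = "Oz")), "Oz")
})

test_that("rest normalization is a guarded ratio", {
  expect_equal(normalize_by_rest(3, 3), 1)
  expect_equal(normalize_by_rest(6, 3), 2)
  expect_equal(normalize_by_rest(6, 3, log = TRUE), log(2))
  expect_error(normalize_by_rest(1, 0), "positive")
})
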