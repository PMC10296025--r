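test_that("coherence of a signal with an identical copy is 1", {
  set.seed(2)
  x <- eegattn:::narrowband_noise(50000, 500, c(4, 8), 3) + rnorm(50000)
  ep <- make_epochs(recording(rbind(x, x), 500, channels = c("Fz", "Pz")), 5)
  cm <- coherency(ep, band_spec("theta", 4, 8))
  expect_equal(cm$matrix["Fz", "Pz"], 1, tolerance = 1e-6)
  expect_equal(unname(diag(cm$matrix)), rep(1, 2))
})

test_that("independent channels show low coherence that shrinks with data", {
  mk <- function(n_epochs, seed) {
    set.seed(seed)
    make_epochs(recording(matrix(rnorm(2 * n_epochs * 2500), 2), 500,
                          channels = c("Fz", "Pz")), 5)
  }
  few <- coherency(mk(5, 1), band_spec("theta", 4, 8))$matrix["Fz", "Pz"]
  many <- coherency(mk(100, 2), band_spec("theta", 4, 8))$matrix["Fz", "Pz"]
  expect_lt(many, 0.2)
  expect_lt(many, few)
})

test_that("common-source coherence matches Ps/(Ps+Pn) on long signals", {
  ep <- common_source_epochs(n_sec = 100, src_rms = 2, noise_sd = 2,
                             band = c(3.5, 8.5))
  est <- coherency(ep, band_spec("theta", 4, 8))$matrix["Fz", "Pz"]
  ps <- 2^2 / 5                # flat density over the 5 Hz source band
  pn <- 2^2 / 250
  expect_equal(est, ps / (ps + pn), tolerance = 0.05)
})

test_that("coherence is invariant to channel scaling, symmetric, bounded", {
  ep <- common_source_epochs(n_sec = 50, seed = 21)
  cm <- coherency(ep, band_spec("theta", 4, 8))
  ep2 <- ep
  ep2$data[, 1, ] <- ep2$data[, 1, ] * 13.7
  cm2 <- coherency(ep2, band_spec("theta", 4, 8))
  expect_equal(cm2$matrix, cm$matrix, tolerance = 1e-10)
  expect_equal(cm$matrix, t(cm$matrix))
  expect_true(all(cm$matrix >= 0 & cm$matrix <= 1 + 1e-12))
  # a single Welch window is a degenerate estimate and is refused
  short <- ep
  short$data <- ep$data[1, , 1:256, drop = FALSE]
  expect_error(coherency(short, band_spec("theta", 4, 8)), "single-window")
})

test_that("band coherence between targets never falls as shared amplitude rises", {
  cohs <- vapply(c(0, 1, 2, 4, 8), function(amp) {
    cfg <- small_config(duration = 90, n_subjects = 1, background_rms = 5,
                        noise_sd = 1, blink_rate = 0,
                        oscillator_specs = if (amp > 0) list(
                          source_spec(c(4, 8), c("Fz", "Pz"),
                                      c(planned = amp), shared = TRUE))
                        else list())
    ep <- make_epochs(generate_recording(cfg, 1, "planned"), 5)
    coherency(ep, band_spec("theta", 4, 8))$matrix["Fz", "Pz"]
  }, 0)
  expect_true(all(diff(cohs) > -0.05))   # monotone up to estimator noise
  expect_gt(cohs[5], cohs[1] + 0.3)
})

test_that("CSD maps a uniform field to zero and sharpens focal activity", {
  ep <- make_epochs(recording(matrix(3, 32, 2500), 500), 5)
  expect_lt(max(abs(current_source_density(ep)$data)), 1e-8)

  # focal source at Fz mixed into all channels by smooth volume conduction
  set.seed(12)
  src <- eegattn:::narrowband_noise(15000, 500, c(4, 8), 5)
  pos <- eeg_montage()
  gain <- exp(-2 * as.vector(sqrt(rowSums(sweep(pos, 2, pos["Fz", ])^2))))
  X <- outer(gain, src) + matrix(rnorm(32 * 15000, 0, 0.1), 32)
  ep2 <- make_epochs(recording(X, 500), 5)
  csd <- current_source_density(ep2)
  # spatial autocorrelation between neighbouring channels must drop
  neigh <- function(e) {
    m <- cor(t(e$data[1, , ]))
    mean(m[cbind(match(c("Fz", "Fz", "Fz"), e$channels),
                 match(c("F3", "F4", "Cz"), e$channels))])
  }
  expect_lt(neigh(csd), neigh(ep2))
  # missing positions are an error
  bad <- ep2; bad$montage <- pos[1:10, ]
  expect_error(current_source_density(bad), "positions")
})

test_that("region-pair averaging uses bipartite pairs across and distinct pairs within regions", {
  chans <- eegattn:::eeg_channels()
  M <- matrix(0.37, 32, 32, dimnames = list(chans, chans))
  diag(M) <- 1
  expect_equal(region_pair_coherence(M, c("Frontal", "Parietal")), 0.37)
  # within-region: 7 frontal channels -> choose(7,2) = 21 unordered pairs
  frontal <- eeg_regions()$Frontal
  M2 <- M
  M2[frontal[1], frontal[2]] <- M2[frontal[2], frontal[1]] <- 1.0
  expect_equal(region_pair_coherence(M2, c("Frontal", "Frontal")),
               (20 * 0.37 + 1) / 21)
  expect_error(region_pair_coherence(M, c("Frontal", "Nowhere")),
               "Nowhere")
})
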