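---
title: "Spectral EEG markers of goal-driven and stimulus-driven attention: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral EEG markers of goal-driven and stimulus-driven attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

When a shopper walks a supermarket with a list, attention is directed by an
internal goal (top-down); when they browse freely, it is captured by the
shelves (bottom-up). Scalp EEG carries candidate signatures of this
distinction: frontal-midline theta power (4–8 Hz) rises with goal
maintenance, posterior and frontal alpha (8–13 Hz) falls during external
sensory intake, theta-band synchronization across the frontoparietal
network increases under goal-driven control, and the spectral entropy of
the signal rises when activity becomes broadband and irregular under
stimulus-driven attention.

`eegattn` implements the full analysis chain for a two-condition
(planned vs. unplanned purchase) study of this kind — 32-channel EEG at
500 Hz, a 30 s eyes-closed rest baseline, several minutes per shopping
condition — together with a seeded synthetic-data generator that emulates
recordings with these effects planted, so every stage can be validated
against a known ground truth even though raw EEG from such studies is
rarely shareable.

## The synthetic study

`sim_config()` encodes the emulated study conditions: 29 subjects; one
rest (30 s), one planned and one unplanned recording each; condition
durations drawn per subject from truncated normals with means 238.87 s
(planned) and 228.00 s (unplanned), SDs 85.57 and 107.20 s and a 60 s
floor, reflecting the high between-subject variance such tasks produce; a
behavioral log in which every completing subject buys exactly the six
listed items (so 29 × 6 = 174 planned purchases) and a Poisson number of
unplanned items averaging 172/29 per subject.

Each channel is the sum of:

* a 1/f^β background (β = 1, RMS 10 µV), generated by spectrally shaping
  white Gaussian noise in the frequency domain;
* band-limited oscillators, generated as band-pass-filtered Gaussian noise
  rather than sinusoids — EEG rhythms are stochastic, and stochastic
  narrowband sources make coherence controllable: a *shared* source is one
  latent time series projected to several channels (creating true
  inter-channel coherence), while independent per-channel oscillators move
  band power only;
* white sensor noise (SD 2 µV);
* eye blinks: 400 ms raised-cosine transients at 12 events/min, peak
  amplitude 10× the background RMS at the frontopolar sites, spatial
  weight proportional to the squared positive anterior montage coordinate
  (maximal at Fp1/Fp2, zero posteriorly).

The default planted sources implement the contrasts the analysis is meant
to detect: frontal-midline theta (Fz, FC1, FC2, Cz) at 5 µV RMS when
planned vs. 2 µV otherwise; a shared frontoparietal theta source mixed at
4 µV planned vs. 1.5 µV otherwise; frontal/parietal alpha at 4 µV except
1.5 µV when unplanned; and a narrow ~10 Hz rhythm at Fp1, F7, Oz and P8
present only in the planned condition, which concentrates those channels'
spectra and lowers their spectral entropy relative to the unplanned
condition. Every recording's random stream derives deterministically from
`(seed, subject, condition)`, so studies are bit-reproducible and any
single recording can be regenerated in isolation.

What the generator does *not* emulate: realistic head-model forward
mixing (channels share sources only where a shared spec says so, plus
whatever the common average reference introduces), non-stationarity within
a phase (navigation vs. product inspection), saccade and EMG artifacts,
and line noise. Passing tests therefore demonstrate correctness of the
estimators and the planted-effect logic, not performance on real
recordings.

## Preprocessing

The chain follows standard practice for this kind of recording, in this
order: band-pass, notch, ICA-based artifact removal, common average
reference, 5 s epoching.

* **Band-pass 0.1–100 Hz.** Hamming-windowed linear-phase sinc FIR,
  applied zero-phase (symmetric kernel, FFT convolution, group-delay
  compensation, odd-reflection edge padding) so no condition-differential
  lag is introduced. The order follows from the transition bandwidth,
  which defaults to the low cutoff: the stop-band (≈53 dB for a Hamming
  design) then begins one octave below the band edge. A 0.1 Hz edge at
  500 Hz thus implies a ~16500-tap kernel; within one kernel half-length
  of the recording edges the attenuation guarantee does not hold (filter
  tests measure the steady-state region), which is immaterial for
  band-limited content but worth knowing.
* **Notch 50 Hz.** Second-order Butterworth band-stop (±2 Hz) applied
  forward–backward: essentially complete rejection at the line frequency,
  under 3 dB at ±5 Hz.
* **Artifact components.** The study this emulates removed ICA components
  by visual inspection — on average 9.5 of 32 per subject on real data —
  which is not testable; `remove_artifact_components()` substitutes two
  automated criteria targeting exactly the phenotypes that inspection
  removes: (a) component time course correlating > 0.8 with the Fp1/Fp2
  mean (blinks and vertical eye movement), and (b) component PSD *rising*
  with frequency (log–log slope over 5–45 Hz above 0.1; muscle/broadband
  noise). The small positive slope margin is deliberate: a strict "slope
  > 0" rule flips on estimator noise for flat-spectrum components. The
  decomposition is a symmetric fixed-point ICA with tanh contrast after
  PCA whitening, capped at 64 iterations — the 1/f background is Gaussian,
  for which ICA rotation cannot converge (and need not: the non-Gaussian
  artifact components separate within a few dozen iterations). Counts of
  removed components on synthetic data are reported, not asserted, since
  they need not match the real-data figure. Recordings shorter than 60 s
  (the rest baseline) are passed through with a note rather than
  decomposed.
* **Average reference, epoching.** The per-sample channel mean is
  subtracted (exact zero-mean property, idempotent), then the recording is
  cut into consecutive non-overlapping 5 s epochs, dropping the remainder.
  Non-overlap keeps epochs exchangeable for the permutation test.

One consequence of the common average reference worth stating: a strong
*global* condition effect (e.g. theta raised at 10 of 32 channels) leaks,
with opposite sign, into every other channel via the subtracted mean. A
"no-effect channel" in a referenced montage is therefore only
approximately null; the package's tests check exact nulls on a study
whose planted effects are zeroed, and check that residual shifts at
unplanted channels are small relative to planted ones.

## Spectral features

PSDs use Welch's method: 256-sample (512 ms) Hamming-tapered segments,
50% overlap (the study specifies the window, not the overlap; 50% is the
field's default), averaged periodograms, one-sided scaling satisfying
Parseval (integrated PSD ≈ variance, verified to 5% in tests). Band power
is the *mean* of the PSD bins in a half-open band [f_low, f_high) — the
6 Hz grid bin counts toward theta, the 8 Hz bin toward alpha, never both.
Alpha is 8–13 Hz throughout. Regional summaries average over epochs
first, then over the region's channels (Frontal: Fp1, Fp2, F8, F4, Fz,
F3, F7; Parietal: P7, P3, Pz, P4, P8; Temporal: T7, T8, TP9, TP10, FT9,
FT10; Occipital: O1, O2, Oz; Central: FC5, FC1, FC2, FC6, C3, Cz, C4,
CP5, CP1, CP2, CP6), in linear units. Rest normalization is the plain
ratio condition/rest (log-ratio available via a flag).

## Connectivity

Volume conduction inflates sensor-space synchrony, so connectivity is
estimated on current source density: a spherical-spline surface Laplacian
(stiffness m = 4, regularization λ = 1e−5, 50 Legendre terms — standard
defaults, exposed as arguments) using idealised unit-sphere 10–20
positions. The transform is a fixed linear operator; a uniform field maps
to zero and focal activity is spatially sharpened (both tested).

Coherence between channels X and Y is |S_XY| / √(S_XX · S_YY) per
frequency bin, averaged over the theta bins. The cross-spectra are
averaged across *all* 256-point Welch windows of all epochs of a
condition before the ratio is formed. This averaging order is essential:
coherence computed from a single window is identically 1 for every pair,
so the estimator refuses single-window input. The magnitude (not the
complex coherency) is reported, which is what keeps values in [0, 1].
Estimator facts verified in tests: self-coherence is exactly 1;
independent channels give small values that shrink with the window count;
a shared source s against independent noise n converges to the analytic
P_s/(P_s+P_n); scaling a channel changes nothing. Region-pair summaries
average the full bipartite pair set across two regions, and all distinct
unordered pairs (no self-pairs) within one.

## Spectral entropy

The normalized power spectrum over 0.5–32 Hz (the 16 bins of the
256-point grid at 500 Hz falling in that range) is treated as a
probability distribution; its Shannon entropy divided by log N gives a
value in [0, 1] — 0 for a one-bin spectrum, 1 for a flat one, log k/log N
for k equal bins, independent of logarithm base and of overall power
scaling. Entropy is computed per epoch and averaged (computing it on the
condition-average PSD is possible but mixes within- and between-epoch
structure; the per-epoch route matches how the other features are
produced). Condition tables report planned, unplanned, and their
difference as unplanned − planned, so a positive difference means the
unplanned condition is more irregular.

## Statistics

Condition durations — and hence trial counts — differ systematically, so
parametric pooling is avoided. The test statistic is the mean over
subjects of the difference of within-subject trial means. The null
distribution re-assigns, *within each subject*, the pooled trials to
pseudo-conditions of the original sizes (1000 times by default); the
within-subject scheme respects the subject-paired design implied by
subject-wise differencing, and a pooled variant is available via a flag.
The two-sided p-value uses the add-one estimator (1 + #{|null| ≥
|observed|}) / (n_perm + 1), which cannot return 0. Calibration is
verified by simulation: the empirical type-I rate at α = 0.05 over 1000
null studies with unequal trial counts lands in [0.03, 0.07]. Family-wise
control is Bonferroni with the exact threshold (0.05/32 = 0.0015625 for a
32-channel family — note the exact value, not the rounded 0.001) and a
strict inequality at the boundary.

## Classification

Discriminability of planned vs. unplanned is measured with an RBF-kernel
SVM over three feature families: regional band powers (theta, alpha × 5
regions), theta region-pair coherences, and per-channel spectral
entropies. Coherence needs window averaging, so connectivity features are
estimated on consecutive non-overlapping blocks of 5 epochs, each epoch
carrying its block's value; kernel, cost (1) and gamma (1/p) are exposed.
Evaluation is subject-independent: grouped 5-fold cross-validation in
which no subject contributes epochs to both sides of a fold (asserted in
code), features standardized with training-fold statistics only, and
per-fold ROC AUC reported as mean ± SD alongside accuracy, precision,
recall and F1. Controls verified in tests: near-ceiling AUC (≥ 0.95) on a
strongly separable synthetic study and chance-level AUC (0.5 ± 0.1) after
within-subject label permutation.

## Numerical and design choices, in brief

* Oscillators as filtered noise, not sinusoids; shared latent sources for
  coherence, independent ones for power-only effects.
* Half-open band edges; Methods-section alpha (8–13 Hz) over the
  introduction's looser 8–12.
* Welch overlap 50%; linear (not dB) averaging before regional means.
* Coherence: cross-spectra averaged over all windows before the ratio;
  magnitude reported.
* CSD: spherical spline, m = 4, λ = 1e−5, idealized positions.
* ICA: automated two-criterion rejection in place of manual inspection;
  slope margin 0.1; iteration cap 64.
* Permutation test: within-subject shuffling, add-one two-sided p.
* EDF writing truncates to whole 1 s records; the sidecar table keeps
  exact durations; round-trip error is bounded by one 16-bit quantization
  step.
* Entropy table differences follow the unplanned − planned convention.

## Problem sizes used in the test suite

The generator's defaults describe the full emulated study (29 subjects,
~4 min conditions). The validation suite runs the same machinery at
reduced size — planted-effect recovery on 8 subjects with ~80 s
conditions, the zero-effect null on 6 subjects, classifier controls on 10
subjects with 60 s conditions, statistical calibration on 20-subject
feature-level simulations — with effect sizes, noise levels, blink rates
and all estimator parameters at their defaults. An end-to-end
`run_all()` example at this scale:

```{r example}
library(eegattn)
cfg <- pipeline_config(
  sim = sim_config(n_subjects = 4,
                   condition_duration_mean = c(planned = 90, unplanned = 90),
                   condition_duration_sd = c(planned = 15, unplanned = 15),
                   seed = 7),
  n_perm = 1000, folds = 4, seed = 7)
res <- run_all(cfg, "eegattn_demo")
res$coherence       # region-pair theta coherence, mean ± SD across subjects
res$stats           # permutation contrasts, Bonferroni-flagged
res$classification  # per-feature-set AUC mean ± SD
```

## Limitations

Synthetic validation cannot certify performance on real EEG: real
artifacts are more varied than the planted blink class, real sources mix
through a head model rather than a designated channel list, and real
effect sizes are far smaller than the planted defaults. The reported
coherence and entropy magnitudes depend on estimator settings (window
length, block size) as well as on the data, so only directions and
statistical decisions — not printed magnitudes from any particular real
study — should be compared across implementations. The ICA substitute is
deliberately conservative; heavily contaminated recordings curated by an
expert may be cleaned more aggressively than this automation.
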