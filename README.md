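# eegattn

Spectral EEG markers of goal-driven vs. stimulus-driven attention, with a
planted-truth synthetic study generator.

## What this is for

Consumer-neuroscience and attention researchers contrast two modes of
attention: **top-down** (goal-driven — e.g. shopping from a list, the
*planned purchase* condition) and **bottom-up** (stimulus-driven — free
browsing, the *unplanned purchase* condition). Scalp EEG carries candidate
markers of that distinction, and `eegattn` implements the complete analysis
chain for a 32-channel, 500 Hz, two-condition-plus-rest study design:

1. **Preprocessing** — zero-phase FIR band-pass (0.1–100 Hz, Hamming
   windowed-sinc), 50 Hz notch, automated ICA artifact-component rejection
   (blink-correlated and rising-spectrum components), common average
   reference, 5 s epoching; EDF input/output.
2. **Band power** — Welch PSD (256-sample Hamming windows, 50 % overlap),
   mean power in theta `[4, 8)` and alpha `[8, 13)` Hz per channel and scalp
   region, optionally normalized by the resting baseline.
3. **Connectivity** — surface-Laplacian current source density
   (spherical spline, m = 4, λ = 1e−5), then magnitude coherence

   `Coh_XY(f) = |S_XY(f)| / sqrt(S_XX(f) · S_YY(f))`

   from window-averaged cross-spectra, averaged over theta bins and over
   region pairs (frontal–frontal, frontal–parietal, parietal–parietal).
4. **Spectral entropy** — Shannon entropy of the normalized PSD over
   0.5–32 Hz, scaled by `1/log N` into [0, 1]:

   `SE = (1/log N) · Σ_i P_n(f_i) · log(1 / P_n(f_i))`

5. **Statistics** — a within-subject trial-label permutation test built for
   unequal trial counts (subject-mean difference statistic, add-one
   two-sided p), Bonferroni control with the exact threshold (0.05/32 =
   0.0015625).
6. **Classification** — subject-independent (grouped) 5-fold RBF-SVM with
   per-fold ROC AUC, over PSD, connectivity and entropy feature sets.

Because raw EEG of such studies is typically unavailable, the package
includes a first-class **synthetic-data module**: 1/f background,
band-limited stochastic oscillators (independent for power effects, shared
latent sources for true coherence), eye-blink artifacts, per-subject
condition durations, and a behavioral purchase log — all bit-reproducible
from a single seed. Every estimator is validated against analytic oracles
(Parseval, self-coherence = 1, common-source coherence = Ps/(Ps+Pn),
entropy closed forms, type-I calibration) and against the planted effects.

## Worked example

A reduced four-subject study with the default planted effects,
end-to-end:

```r
library(eegattn)
cfg <- pipeline_config(
  sim = sim_config(n_subjects = 4,
                   condition_duration_mean = c(planned = 90, unplanned = 90),
                   condition_duration_sd = c(planned = 15, unplanned = 15),
                   seed = 7),
  n_perm = 1000, folds = 4, seed = 7)
res <- run_all(cfg, "eegattn_demo")
```

`res$coherence` — theta coherence after CSD, mean ± SD across subjects;
the shared frontoparietal theta source is mixed more strongly in the
planned condition, and the pipeline recovers exactly that:

```
 condition              pair   mean      sd
   planned   Frontal-Frontal 0.1677 0.00493
 unplanned   Frontal-Frontal 0.1248 0.00739
   planned  Frontal-Parietal 0.1902 0.00367
 unplanned  Frontal-Parietal 0.1075 0.00695
   planned Parietal-Parietal 0.1833 0.00635
 unplanned Parietal-Parietal 0.0942 0.00715
```

`res$stats` — permutation contrasts (planned − unplanned), e.g.:

```
              feature observed  p_value significant
        theta_Frontal   1.9396 0.000999        TRUE   # theta up when planned
       alpha_Parietal   3.9209 0.000999        TRUE   # alpha down when unplanned
 coh_Frontal_Parietal   0.0682 0.000999        TRUE   # coherence up when planned
              spe_Fp1  -0.0333 0.000999        TRUE   # entropy up when unplanned
```

`res$classification` — subject-independent SVM discriminability per
feature set (the planted default effects are deliberately strong, so AUCs
sit near the ceiling):

```
AUC[psd         ] = 1.000 +/- 0.000
AUC[connectivity] = 0.988 +/- 0.010
AUC[spe         ] = 0.992 +/- 0.016
AUC[all         ] = 1.000 +/- 0.000
```

The run directory additionally contains the generated EDFs, the behavioral
log (for the default 29-subject configuration the planned purchases total
29 × 6 = 174), per-channel entropy and coherence tables as CSV, the
preprocessing reports, and a manifest with the configuration hash and all
seeds. A command-line front-end for the same pipeline is installed at
`inst/scripts/eeg_pipeline.R`:

```sh
Rscript inst/scripts/eeg_pipeline.R --config inst/extdata/example_config.yaml --out run/
```

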