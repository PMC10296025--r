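# Example pipeline configuration: a reduced four-subject study with the
# default planted effects. All omitted fields keep their package defaults
# (29 subjects, 238.87/228.00 s mean condition durations, 0.1-100 Hz
# band-pass, 50 Hz notch, 5 s epochs, 256-sample Welch windows, theta 4-8 /
# alpha 8-13 Hz, entropy over 0.5-32 Hz, 1000 permutations, 5 folds).
sim:
  n_subjects: 4
  condition_duration_mean:
    planned: 90
    unplanned: 90
  condition_duration_sd:
    planned: 15
    unplanned: 15
  seed: 7
n_perm: 1000
folds: 4
seed: 7
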