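# Frozen generator presets (6 classes, 3 sensors x 80 samples, volts).
# "overlapping" was calibrated once by simulation so that a baseline
# ANN-3-50 with 7 train / 5 test trials per class lands in the 55-80%
# accuracy band, then frozen.
separable:
  n_classes: 6
  delta: 0.6
  sd_amp: 0.02
  sd_tau: 0.02
  sd_noise: 0.01
overlapping:
  n_classes: 6
  delta: 0.25
  sd_amp: 0.08
  sd_tau: 0.10
  sd_noise: 0.03
chance:
  n_classes: 6
  delta: 0.0
  sd_amp: 0.05
  sd_tau: 0.05
  sd_noise: 0.02
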