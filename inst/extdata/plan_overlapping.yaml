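# Example benchmark plan: the study protocol run on the packaged
# "overlapping" generator preset (6 classes, 12 trials/class, 7 train +
# 5 test per class, 10 trainings per condition).
scenario: overlapping
trials_per_class: 12
train_per_class: 7
test_per_class: 5
sizes: [0, 100, 500, 2000]
repeats: 10
seed: 1
augment:
  method: interp_extrap
  k: 3
  c1: -2.0
  c2: 3.0
  sigma: 0.05
  stretch_alpha: 0.1
classifiers:
  - {kind: ann, nl: 3, nu: 50}
  - {kind: msvm}
  - {kind: rf, n_trees: 100}
  - {kind: pca_msvm, nv: 3}
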