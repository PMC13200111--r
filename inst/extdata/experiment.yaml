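# Paper-shaped synthetic QA experiment, scaled for a desktop run.
# spots_per_layer: 725 reproduces the full-scale campaign (928,000 spots).
seed: 1
spots_per_layer: 100
include_fault: true
tolerances:
  annual_mm: 1.0
  daily_mm: 2.0
  window: 50
model:
  n_trees: 500
  learning_rate: 0.1
dose:
  enabled: true
  spacing: 4.0
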