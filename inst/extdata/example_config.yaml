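# Small end-to-end example run (minutes of compute, not hours).
seed: 1
population:
  n_cells: 60
  n_targets: 5
protocol:
  repeats_main: 10
  repeats_selection: 5
experiment:
  conditions: [control, stim16]
  n_fov_per_condition: 2
simulation:
  n_per_fov: 50
  n_fov: 6
output:
  figures: true
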