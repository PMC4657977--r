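# Choice-assay experiment: circular dish with a Gaussian odour source near
# the left wall; larvae start on the vertical centre line.
name: choice_assay_example
larva:
  v_forward: 1.0
mechanisms:
  run_term: true
  cast_term: true
  weathervane: true
  scaling: 1.0
landscape:
  kind: gaussian
  peak: [-40, 0]
  sigma: 30
arena:
  kind: circle
  radius: 45
protocol:
  n_larvae: 40
  duration: 300
  start: {kind: line, from: [0, -44], to: [0, 44]}
seed: 1
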