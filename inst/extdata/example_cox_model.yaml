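kind: cox
coefficients:
  fit: 0.72
  age: 0.042
  sex: 0.35
  haemoglobin: -0.025
  mcv: -0.04
  platelets: 0.0025
transforms:
  fit: log1p
  age: identity
  sex: identity
  haemoglobin: identity
  mcv: identity
  platelets: identity
baseline_survival_at_horizon: 0.95320323307808
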