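kind: logistic
coefficients:
  fit: 0.75
  age: 0.045
  sex: 0.35
  haemoglobin: -0.026
  mcv: -0.042
  platelets: 0.0026
transforms:
  fit: log1p
  age: identity
  sex: identity
  haemoglobin: identity
  mcv: identity
  platelets: identity
intercept: -2.99392861497705
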