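cohort_label: validation
'n': 100000
seed: 1
recent_fbc_probability: 0.91
marginals:
  age:
    probs:
    - 0.001
    - 0.05
    - 0.25
    - 0.5
    - 0.75
    - 0.9
    - 0.95
    - 0.99
    - 0.999
    - 1.0
    values:
    - 18.0
    - 26.0
    - 35.0
    - 45.0
    - 58.0
    - 70.0
    - 78.0
    - 86.0
    - 93.0
    - 100.0
    transform: identity
    lower_bound: 18.0
    upper_bound: 100.0
  sex:
    probs:
    - 0.58
    - 1.0
    values:
    - 0.0
    - 1.0
    transform: identity
    binary: yes
  fit:
    probs:
    - 0.3
    - 0.5
    - 0.7
    - 0.8
    - 0.9
    - 0.95
    - 0.99
    - 0.999
    - 1.0
    values:
    - 0.0
    - 1.8
    - 5.0
    - 9.0
    - 24.0
    - 68.0
    - 400.0
    - 1200.0
    - 3000.0
    transform: log
    lower_bound: 0.0
    upper_bound: 3000.0
  haemoglobin:
    probs:
    - 0.001
    - 0.01
    - 0.25
    - 0.5
    - 0.75
    - 0.99
    - 1.0
    values:
    - 60.0
    - 95.0
    - 127.0
    - 137.0
    - 147.0
    - 172.0
    - 195.0
    transform: identity
    lower_bound: 50.0
    upper_bound: 200.0
  mcv:
    probs:
    - 0.001
    - 0.01
    - 0.25
    - 0.5
    - 0.75
    - 0.99
    - 1.0
    values:
    - 55.0
    - 72.0
    - 86.0
    - 90.0
    - 94.0
    - 103.0
    - 125.0
    transform: identity
    lower_bound: 50.0
    upper_bound: 130.0
  platelets:
    probs:
    - 0.001
    - 0.01
    - 0.25
    - 0.5
    - 0.75
    - 0.99
    - 1.0
    values:
    - 40.0
    - 140.0
    - 218.0
    - 258.0
    - 306.0
    - 540.0
    - 990.0
    transform: log
    lower_bound: 20.0
    upper_bound: 1200.0
correlation:
- - 1.0
  - 0.0
  - 0.15
  - -0.15
  - 0.2
  - -0.08
- - 0.0
  - 1.0
  - 0.05
  - 0.35
  - 0.0
  - -0.15
- - 0.15
  - 0.05
  - 1.0
  - -0.25
  - -0.15
  - 0.18
- - -0.15
  - 0.35
  - -0.25
  - 1.0
  - 0.3
  - 0.0
- - 0.2
  - 0.0
  - -0.15
  - 0.3
  - 1.0
  - -0.12
- - -0.08
  - -0.15
  - 0.18
  - 0.0
  - -0.12
  - 1.0
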