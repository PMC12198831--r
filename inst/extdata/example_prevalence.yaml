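crc_stage_distribution:
  I: 0.24
  II: 0.26
  III: 0.31
  IV: 0.19
hr_adenoma_prevalence:
  fit_ge10: 0.08
  fit_lt10: 0.015
lr_adenoma_prevalence: 0.1
ibd_prevalence:
- age_lo: 18.0
  age_hi: 30.0
  fit_stratum: ge10
  prob: 0.09
- age_lo: 30.0
  age_hi: 40.0
  fit_stratum: ge10
  prob: 0.07
- age_lo: 40.0
  age_hi: 50.0
  fit_stratum: ge10
  prob: 0.05
- age_lo: 50.0
  age_hi: 60.0
  fit_stratum: ge10
  prob: 0.035
- age_lo: 60.0
  age_hi: 70.0
  fit_stratum: ge10
  prob: 0.025
- age_lo: 70.0
  age_hi: 80.0
  fit_stratum: ge10
  prob: 0.018
- age_lo: 80.0
  age_hi: 101.0
  fit_stratum: ge10
  prob: 0.012
- age_lo: 18.0
  age_hi: 30.0
  fit_stratum: lt10
  prob: 0.012
- age_lo: 30.0
  age_hi: 40.0
  fit_stratum: lt10
  prob: 0.009
- age_lo: 40.0
  age_hi: 50.0
  fit_stratum: lt10
  prob: 0.007
- age_lo: 50.0
  age_hi: 60.0
  fit_stratum: lt10
  prob: 0.005
- age_lo: 60.0
  age_hi: 70.0
  fit_stratum: lt10
  prob: 0.004
- age_lo: 70.0
  age_hi: 80.0
  fit_stratum: lt10
  prob: 0.003
- age_lo: 80.0
  age_hi: 101.0
  fit_stratum: lt10
  prob: 0.002
prevalence_scaling: 1.0
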