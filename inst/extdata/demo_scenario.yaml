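label: demo (latent rho = 0.30)
'n': 200000
factors:
- smoking
- hypertension
- diabetes
- elevated_cholesterol
- excess_body_weight
prevalence:
- 0.649
- 0.3
- 0.056
- 0.396
- 0.25
rr_true:
- 1.5164
- 1.9
- 1.7829
- 1.5468
- 1.3
latent_correlation:
- - 1.0
  - 0.3
  - 0.3
  - 0.3
  - 0.3
- - 0.3
  - 1.0
  - 0.3
  - 0.3
  - 0.3
- - 0.3
  - 0.3
  - 1.0
  - 0.3
  - 0.3
- - 0.3
  - 0.3
  - 0.3
  - 1.0
  - 0.3
- - 0.3
  - 0.3
  - 0.3
  - 0.3
  - 1.0
baseline_risk: 0.05
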