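outcome: symptoms
measurement:
  MD:
  - md1
  - md2
  - md3
  - md4
  - md5
  TL:
  - trauma
covariates: []
interactions:
- - MD
  - TL
latent_covariate_interactions: []
family: negbin
scaling: standardized
constraints:
  fixed_reliability:
    trauma: 0.82
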