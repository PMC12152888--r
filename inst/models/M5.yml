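kind: transfer_model
id: M5
response_transform: log10
units: mg/L
intercept: -0.257
terms:
- feature: cd_msm_mgL
  transform: log10
  coefficient: 0.572
- feature: ph
  transform: identity
  coefficient: 0.106
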