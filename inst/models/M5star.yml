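kind: transfer_model
id: M5star
response_transform: log10
units: mg/L
intercept: 0.385
terms:
- feature: cd_msm_mgL
  transform: log10
  coefficient: 0.69
- feature: ph
  transform: identity
  coefficient: 0.02
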