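kind: transfer_model
id: M2
response_transform: log10
units: mg/kg
intercept: 0.114
terms:
- feature: cd_total_mgkg
  transform: log10
  coefficient: 0.955
- feature: ph
  transform: identity
  coefficient: -0.118
- feature: cec_cmolkg
  transform: identity
  coefficient: -0.01
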