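kind: transfer_model
id: M1
response_transform: log10
units: mg/kg
intercept: -0.718
terms:
- feature: cd_total_mgkg
  transform: log10
  coefficient: 0.906
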