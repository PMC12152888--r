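kind: transfer_model
id: M4
response_transform: log10
units: mg/kg
intercept: -0.768
terms:
- feature: cd_cacl2_mgkg
  transform: log10
  coefficient: 0.509
- feature: ph
  transform: identity
  coefficient: 0.104
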