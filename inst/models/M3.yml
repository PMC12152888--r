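kind: bcf_model
id: M3
a: 0.014
b: -0.236
c: 1.113
domain:
- 3.97
- 8.55
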