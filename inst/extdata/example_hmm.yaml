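hidden_alphabet:
- S
- G
observed_alphabet:
- a
- b
initial:
- 0.6
- 0.4
transitions:
- - 0.7
  - 0.3
- - 0.4
  - 0.6
emissions:
- - 0.9
  - 0.1
- - 0.2
  - 0.8
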