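constructs:
- name: toy-midi
  segments:
  - NTD
  - domain: H1
    keep_start: 9
    keep_end: 20
  - R1
  - CT
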