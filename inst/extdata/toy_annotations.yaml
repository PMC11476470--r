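domains:
- name: NTD
  start: 1
  end: 30
  category: terminal
- name: H1
  start: 31
  end: 50
  category: hinge
- name: R1
  start: 51
  end: 90
  category: repeat
- name: CT
  start: 91
  end: 120
  category: c-terminal
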