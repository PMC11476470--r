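designs:
- name: toy-split
  construct: toy-midi
  split_after: 63
  n_tag_seq: YPYDVPDYA
  extein_window: 20
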