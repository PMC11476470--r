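domains:
- name: ABD1
  start: 1
  end: 246
  category: terminal
- name: H1
  start: 247
  end: 342
  category: hinge
- name: R1
  start: 343
  end: 451
  category: repeat
- name: R2
  start: 452
  end: 560
  category: repeat
- name: R3
  start: 561
  end: 669
  category: repeat
- name: H2
  start: 670
  end: 719
  category: hinge
- name: R4
  start: 720
  end: 828
  category: repeat
- name: R5
  start: 829
  end: 937
  category: repeat
- name: R6
  start: 938
  end: 1046
  category: repeat
- name: R7
  start: 1047
  end: 1155
  category: repeat
- name: R8
  start: 1156
  end: 1264
  category: repeat
- name: R9
  start: 1265
  end: 1373
  category: repeat
- name: R10
  start: 1374
  end: 1482
  category: repeat
- name: R11
  start: 1483
  end: 1591
  category: repeat
- name: R12
  start: 1592
  end: 1700
  category: repeat
- name: R13
  start: 1701
  end: 1809
  category: repeat
- name: R14
  start: 1810
  end: 1918
  category: repeat
- name: R15
  start: 1919
  end: 2027
  category: repeat
- name: R16
  start: 2028
  end: 2136
  category: repeat
- name: R17
  start: 2137
  end: 2245
  category: repeat
- name: R18
  start: 2246
  end: 2354
  category: repeat
- name: R19
  start: 2355
  end: 2463
  category: repeat
- name: H3
  start: 2464
  end: 2511
  category: hinge
- name: R20
  start: 2512
  end: 2620
  category: repeat
- name: R21
  start: 2621
  end: 2729
  category: repeat
- name: R22
  start: 2730
  end: 2838
  category: repeat
- name: R23
  start: 2839
  end: 2947
  category: repeat
- name: R24
  start: 2948
  end: 3056
  category: repeat
- name: H4
  start: 3057
  end: 3126
  category: hinge
- name: CR
  start: 3127
  end: 3406
  category: cysteine-rich
- name: CT
  start: 3407
  end: 3606
  category: c-terminal
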