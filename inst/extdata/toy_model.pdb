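ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 90.00           N
ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 90.00           C
ATOM      3  CA  GLY A   2       2.000   3.800   0.000  1.00 85.00           C
ATOM      4  CA  SER B   1       5.000   1.000   2.000  1.00 70.00           C
END
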