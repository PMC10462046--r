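Two-bead fixture
    2
    1POPC   PO4    1   1.000   2.000   3.000
    2W        W    2   4.000   5.000   6.000
  10.00000  10.00000  10.00000
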