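REMARK synthetic single-residue POPC headgroup fixture
CRYST1   60.000   60.000   90.000  90.00  90.00  90.00 P 1           1
ATOM      1  N   POPC    1      10.000  10.000  45.000  1.00  0.00           N
ATOM      2  C12 POPC    1      11.200  10.500  44.600  1.00  0.00           C
ATOM      3  P   POPC    1      13.000  11.000  43.000  1.00  0.00           P
ATOM      4  O11 POPC    1      14.100  11.800  42.500  1.00  0.00           O
ATOM      5  C1  POPC    1      15.000  12.000  41.000  1.00  0.00           C
END
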