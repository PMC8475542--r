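REMARK pose reference energy -1492.1571
HETATM    1  C1  LIG X   1       3.300  -0.700   5.300  1.00  0.00           C
HETATM    2  C2  LIG X   1       4.700  -0.700   5.300  1.00  0.00           C
HETATM    3  C3  LIG X   1       3.300   0.700   5.300  1.00  0.00           C
HETATM    4  C4  LIG X   1       4.700   0.700   5.300  1.00  0.00           C
HETATM    5  C5  LIG X   1       3.300  -0.700   6.700  1.00  0.00           C
HETATM    6  C6  LIG X   1       4.700  -0.700   6.700  1.00  0.00           C
HETATM    7  C7  LIG X   1       3.300   0.700   6.700  1.00  0.00           C
HETATM    8  C8  LIG X   1       4.700   0.700   6.700  1.00  0.00           C
END
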