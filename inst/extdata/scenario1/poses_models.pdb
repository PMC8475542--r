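MODEL        1
HETATM    1  C1  LIG X   1      -1.954   3.098   2.300  1.00  0.00           C
HETATM    2  C2  LIG X   1      -0.554   3.098   2.300  1.00  0.00           C
HETATM    3  C3  LIG X   1      -1.954   4.498   2.300  1.00  0.00           C
HETATM    4  C4  LIG X   1      -0.554   4.498   2.300  1.00  0.00           C
HETATM    5  C5  LIG X   1      -1.954   3.098   3.700  1.00  0.00           C
HETATM    6  C6  LIG X   1      -0.554   3.098   3.700  1.00  0.00           C
HETATM    7  C7  LIG X   1      -1.954   4.498   3.700  1.00  0.00           C
HETATM    8  C8  LIG X   1      -0.554   4.498   3.700  1.00  0.00           C
ENDMDL
MODEL        2
HETATM    1  C1  LIG X   1      -4.234  -2.574  -0.700  1.00  0.00           C
HETATM    2  C2  LIG X   1      -2.834  -2.574  -0.700  1.00  0.00           C
HETATM    3  C3  LIG X   1      -4.234  -1.174  -0.700  1.00  0.00           C
HETATM    4  C4  LIG X   1      -2.834  -1.174  -0.700  1.00  0.00           C
HETATM    5  C5  LIG X   1      -4.234  -2.574   0.700  1.00  0.00           C
HETATM    6  C6  LIG X   1      -2.834  -2.574   0.700  1.00  0.00           C
HETATM    7  C7  LIG X   1      -4.234  -1.174   0.700  1.00  0.00           C
HETATM    8  C8  LIG X   1      -2.834  -1.174   0.700  1.00  0.00           C
ENDMDL
MODEL        3
HETATM    1  C1  LIG X   1      -4.520   0.487  11.300  1.00  0.00           C
HETATM    2  C2  LIG X   1      -3.120   0.487  11.300  1.00  0.00           C
HETATM    3  C3  LIG X   1      -4.520   1.887  11.300  1.00  0.00           C
HETATM    4  C4  LIG X   1      -3.120   1.887  11.300  1.00  0.00           C
HETATM    5  C5  LIG X   1      -4.520   0.487  12.700  1.00  0.00           C
HETATM    6  C6  LIG X   1      -3.120   0.487  12.700  1.00  0.00           C
HETATM    7  C7  LIG X   1      -4.520   1.887  12.700  1.00  0.00           C
HETATM    8  C8  LIG X   1      -3.120   1.887  12.700  1.00  0.00           C
ENDMDL
MODEL        4
HETATM    1  C1  LIG X   1      -4.499  -1.953  11.300  1.00  0.00           C
HETATM    2  C2  LIG X   1      -3.099  -1.953  11.300  1.00  0.00           C
HETATM    3  C3  LIG X   1      -4.499  -0.553  11.300  1.00  0.00           C
HETATM    4  C4  LIG X   1      -3.099  -0.553  11.300  1.00  0.00           C
HETATM    5  C5  LIG X   1      -4.499  -1.953  12.700  1.00  0.00           C
HETATM    6  C6  LIG X   1      -3.099  -1.953  12.700  1.00  0.00           C
HETATM    7  C7  LIG X   1      -4.499  -0.553  12.700  1.00  0.00           C
HETATM    8  C8  LIG X   1      -3.099  -0.553  12.700  1.00  0.00           C
ENDMDL
MODEL        5
HETATM    1  C1  LIG X   1      -4.358  -2.319  11.300  1.00  0.00           C
HETATM    2  C2  LIG X   1      -2.958  -2.319  11.300  1.00  0.00           C
HETATM    3  C3  LIG X   1      -4.358  -0.919  11.300  1.00  0.00           C
HETATM    4  C4  LIG X   1      -2.958  -0.919  11.300  1.00  0.00           C
HETATM    5  C5  LIG X   1      -4.358  -2.319  12.700  1.00  0.00           C
HETATM    6  C6  LIG X   1      -2.958  -2.319  12.700  1.00  0.00           C
HETATM    7  C7  LIG X   1      -4.358  -0.919  12.700  1.00  0.00           C
HETATM    8  C8  LIG X   1      -2.958  -0.919  12.700  1.00  0.00           C
ENDMDL
MODEL        6
HETATM    1  C1  LIG X   1      -2.735   2.744  11.300  1.00  0.00           C
HETATM    2  C2  LIG X   1      -1.335   2.744  11.300  1.00  0.00           C
HETATM    3  C3  LIG X   1      -2.735   4.144  11.300  1.00  0.00           C
HETATM    4  C4  LIG X   1      -1.335   4.144  11.300  1.00  0.00           C
HETATM    5  C5  LIG X   1      -2.735   2.744  12.700  1.00  0.00           C
HETATM    6  C6  LIG X   1      -1.335   2.744  12.700  1.00  0.00           C
HETATM    7  C7  LIG X   1      -2.735   4.144  12.700  1.00  0.00           C
HETATM    8  C8  LIG X   1      -1.335   4.144  12.700  1.00  0.00           C
ENDMDL
MODEL        7
HETATM    1  C1  LIG X   1      -4.662  -1.247  -0.700  1.00  0.00           C
HETATM    2  C2  LIG X   1      -3.262  -1.247  -0.700  1.00  0.00           C
HETATM    3  C3  LIG X   1      -4.662   0.153  -0.700  1.00  0.00           C
HETATM    4  C4  LIG X   1      -3.262   0.153  -0.700  1.00  0.00           C
HETATM    5  C5  LIG X   1      -4.662  -1.247   0.700  1.00  0.00           C
HETATM    6  C6  LIG X   1      -3.262  -1.247   0.700  1.00  0.00           C
HETATM    7  C7  LIG X   1      -4.662   0.153   0.700  1.00  0.00           C
HETATM    8  C8  LIG X   1      -3.262   0.153   0.700  1.00  0.00           C
ENDMDL
MODEL        8
HETATM    1  C1  LIG X   1       0.430  -4.537  11.300  1.00  0.00           C
HETATM    2  C2  LIG X   1       1.830  -4.537  11.300  1.00  0.00           C
HETATM    3  C3  LIG X   1       0.430  -3.137  11.300  1.00  0.00           C
HETATM    4  C4  LIG X   1       1.830  -3.137  11.300  1.00  0.00           C
HETATM    5  C5  LIG X   1       0.430  -4.537  12.700  1.00  0.00           C
HETATM    6  C6  LIG X   1       1.830  -4.537  12.700  1.00  0.00           C
HETATM    7  C7  LIG X   1       0.430  -3.137  12.700  1.00  0.00           C
HETATM    8  C8  LIG X   1       1.830  -3.137  12.700  1.00  0.00           C
ENDMDL
MODEL        9
HETATM    1  C1  LIG X   1       3.300  -0.700   5.300  1.00  0.00           C
HETATM    2  C2  LIG X   1       4.700  -0.700   5.300  1.00  0.00           C
HETATM    3  C3  LIG X   1       3.300   0.700   5.300  1.00  0.00           C
HETATM    4  C4  LIG X   1       4.700   0.700   5.300  1.00  0.00           C
HETATM    5  C5  LIG X   1       3.300  -0.700   6.700  1.00  0.00           C
HETATM    6  C6  LIG X   1       4.700  -0.700   6.700  1.00  0.00           C
HETATM    7  C7  LIG X   1       3.300   0.700   6.700  1.00  0.00           C
HETATM    8  C8  LIG X   1       4.700   0.700   6.700  1.00  0.00           C
ENDMDL
END
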