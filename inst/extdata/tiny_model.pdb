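ATOM      1  N   MET A   1      10.000  10.000  10.000  1.00 90.00           N
ATOM      2  CA  MET A   1      11.400  10.000  10.000  1.00 90.00           C
ATOM      3  C   MET A   1      12.000  11.400  10.000  1.00 90.00           C
ATOM      4  O   MET A   1      13.200  11.500  10.000  1.00 90.00           O
ATOM      5  N   LYS A   2      11.300  12.500  10.000  1.00 50.00           N
ATOM      6  CA  LYS A   2      11.800  13.800  10.000  1.00 50.00           C
ATOM      7  C   LYS A   2      13.300  13.900  10.000  1.00 50.00           C
ATOM      8  O   LYS A   2      13.900  14.900  10.000  1.00 50.00           O
ATOM      9  N   VAL A   3      13.900  12.700  10.000  1.00 30.00           N
ATOM     10  CA  VAL A   3      15.300  12.600  10.000  1.00 30.00           C
TER
END
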