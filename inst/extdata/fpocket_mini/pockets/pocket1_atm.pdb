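ATOM      3  CB  ALA A   3       7.100  10.000  10.000  1.00  0.00           C
ATOM      7  NE2 GLN A   7      10.000   7.200  10.000  1.00  0.00           N
ATOM     11  OE1 GLN A  11      10.000  10.000   7.300  1.00  0.00           O
ATOM     15  CD1 LEU A  15      13.000  10.400  10.100  1.00  0.00           C
TER
END
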