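ATOM     21  CB  ALA A  21      27.000  30.000  30.000  1.00  0.00           C
ATOM     25  NZ  LYS A  25      30.000  27.100  30.000  1.00  0.00           N
ATOM     29  OD1 ASP A  29      30.000  30.000  27.200  1.00  0.00           O
TER
END
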