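HEADER pocket 1 alpha spheres
ATOM      1  APOL STP     1      10.000  10.000  10.000  0.00  3.40
ATOM      2  APOL STP     1      11.500  10.200   9.800  0.00  3.10
ATOM      3   POL STP     1       9.200  11.100  10.500  0.00  4.00
ATOM      4   POL STP     1      10.400   9.100  11.200  0.00  3.70
ATOM      5  APOL STP     1      11.000  11.000  11.000  0.00  3.20
ATOM      6   POL STP     1       9.500   9.500   9.500  0.00  3.90
TER
END
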