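HEADER pocket 2 alpha spheres
ATOM      1  APOL STP     2      30.000  30.000  30.000  0.00  3.00
ATOM      2   POL STP     2      31.200  30.500  29.700  0.00  3.30
ATOM      3   POL STP     2      29.400  31.000  30.600  0.00  3.60
ATOM      4  APOL STP     2      30.800  29.200  30.900  0.00  3.10
TER
END
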