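# fixture rotamer library: aa phi psi prob chi1..chi4
# '*' in the phi/psi columns marks a backbone-independent record
A * * 1.000000
S * * 0.600000 64.000
S * * 0.400000 -65.000
C * * 0.500000 -65.000
C * * 0.500000 178.000
V * * 0.700000 175.000
V * * 0.300000 -60.000
L * * 0.600000 -65.000 175.000
L * * 0.400000 -172.000 62.000
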