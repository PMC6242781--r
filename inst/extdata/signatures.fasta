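>sig_Cy_songaricum species=Cynomorium_songaricum role=adulterant
CAATTATTTGAGGTGCATTGTAAGAAGCGT
>sig_Ci_sinensis species=Cistanche_sinensis role=adulterant
CGATGGTCTCCCGTGCGCGAGGATGCACGGCCGG
>sig_B_rossica species=Boschniakia_rossica role=adulterant
ACACTGGCCTCCCGTGCGCAACGACGTGCGGCCGGTC
>sig_O_coerulescens species=Orobanche_coerulescens role=adulterant
GTCTGTCGTGTCGGATGGTGTTGCTTGTTGG
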