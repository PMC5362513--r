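>L702H offset=20 half_width=20 synthetic=true
AAAACTCCATGTGTAACTCCTCCGGAAGTAGAATCTTGCAC
>W742C offset=20 half_width=20 synthetic=true
TCGGCCTTTCCATATCTCTGGGTGAACCCCCTGCACGCCCT
>H875Y offset=20 half_width=20 synthetic=true
AAAGTACAATTAGGATATTCCATATCCCTACACTGTATATG
>F877L offset=20 half_width=20 synthetic=true
CCGAACGTTCTAATAAACGATTCCTTAGCAACAAGTCGCCT
>T878A offset=20 half_width=20 synthetic=true
AGAAAGGTACCGCTGGCATAACTTCACGCCTCCCGCTTGCC
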