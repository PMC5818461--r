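>tRNA-Met-3p|syn1
CGCACCGCGGTTCACGTA
>tRNA-Lys-3p|syn2
CCCTGCTTGGGGATTCCC
>tRNA-Ile-3p|syn3
GGCCGGCCAGGTGGCTCG
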