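>trna_Pro_synthetic synthetic tRNA stand-in (72 nt)
CGCATGCTATGCACCGAAATTTAGTACAATTAGTTACTTGTGCAGCGTCCGGGAACAATACCGAACAATTCC
>trna_Val_synthetic synthetic tRNA stand-in (72 nt)
CCATATTCCTTAGTGCGATCGCTGTGTTTGGCCGGGAGCGCCGCCAGTACAAAGAACCCCATTGCTCAACCG
>trna_Met_synthetic synthetic tRNA stand-in (72 nt)
CACGGTTGATTAGTGGTGTAACGCACTTGTCCCCTTTCTTCTTCACGTAGCATAGACACACCCTTTAATGGC
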