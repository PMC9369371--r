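name	sequence
miR-15a-5p RT	GTCGTATCCAGTGCAGGGTCCGAGGTATTCGCACTGGATACGACCACAAA
miR-15a-5p-F	CGCGTAGCAGCACATAATGG
miR-329-3p RT	GTCGTATCCAGTGCAGGGTCCGAGGTATTCGCACTGGATACGACAAAAAG
miR-329-3p-F	CGCGAACACACCCAGCTAAC
miR-466m-3p RT	GTCGTATCCAGTGCAGGGTCCGAGGTATTCGCACTGGATACGACTGCGTG
miR-466m-3p-F	CGCGCGTACATACACACATACA
miR-466o-3p RT	GTCGTATCCAGTGCAGGGTCCGAGGTATTCGCACTGGATACGACGTCTTA
miR-466o-3p-F	GCGCGTACATACATGCACACA
miR-539-5p RT	GTCGTATCCAGTGCAGGGTCCGAGGTATTCGCACTGGATACGACACACAC
miR-539-5p-F	CGCGGGAGAAATTATCCTTG
miR-669b-5p RT	GTCGTATCCAGTGCAGGGTCCGAGGTATTCGCACTGGATACGACACATGC
miR-669b-5p-F	CGCGAGTTTTGTGTGCATGT
miR-universal R	AGTGCAGGGTCCGAGGTATT
ENSMUST00000127786-F	TCACTCCTGCCTTTCGTGAC
ENSMUST00000127786-R	AACAAGTGGGGTGAGCACAA
ENSMUSG00000098912-F	CAGAACAAGCAGCAAGGCACAAC
ENSMUSG00000098912-R	AGTCAGAACCCGTGAAAATCAGTCC
Clec7a-F	GTGCAGTAAGCTTTCCTGGG
Clec7a-R	TCCCGCAATCAGAGTGAAG
Fnbp1-F	AGATGGAGGAGAGGCGGATTGTG
Fnbp1-R	TCACTATCCCGTCCAGGCACTTC
Elovl2-F	CAACATGTTTGGACCACGAG
Elovl2-R	GGATGAAGGTGGGAAGGTAAG
5730455P16Rik-F	GGTGATGATTTCAGCCTCTCCTTGG
5730455P16Rik-R	AACATTACCCAGCCCTTCAAAGACC
U6-F	CAAATTCGTGAAGCGTTCCA
U6-R	AGTGCAGGGTCCGAGGTATT
U6-RT	GTCGTATCCAGTGCAGGGTCCGAGGTA
GAPDH-F	TTGATCTGAAGTCAGGAATCCC
GAPDH-R	TGTAGACCATGTAGTTGAGGTCA
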