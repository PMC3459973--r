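rsid	group	tag	sequence
rs12722495	group 1	yes	CCTTCCAGTTCCTTGAATACTTCCAA[A/G]TCGCACTTAGGATTGAAACTCACCA
rs41295061	group 1	no	TCTGAAGAACCCAGAAGCGACATTAG[A/C]AAGGGGTTCGTTTCACGGAATCCAA
rs12722522	group 1	no	TCGAAGAAAGAGGGCTCATAATTCCA[C/T]GTCAGGGAAGAGCCGCTGGCCTGCC
rs12722508	group 1	no	TGTTGAAAAGAATAGAACCCACCCAC[A/T]GAAACTATCAGAGATCAAATGTTGT
rs41295049	group 1	no	GTGGTGGTATAACATGCAAATGAGAG[A/G]TGCCCAGGGCAAGAAAACTTGCTCT
rs41295065	group 1	no	AGTGGGAGGAAAAGAGAAGAATCAAC[A/G]TGACTCAGATTTCTGGCTTGCGTAC
rs7909519	group 1	no	AGTATAATAGTCAATATAATTAAAAT[G/T]ATTACTTATGCAGTAATTAATTATG
rs41295063	group 1	no	CACCCAGGCTGGAGTGCAACAGTGCA[A/G]TCTCAGCTCACTGCAACTTCTGCCT
rs11594656	group 2	yes	CCAAGGCGGTTCCTTGGTCTGTAGAG[A/T]GAAGGCATCATAGTGAGAAAAGCCA
rs11597367	group 2	no	TACTGGGATTACAAGTGTGAGCCACC[A/G]CACCCAGCGGTTGTGGGCACTCTGA
rs35285258	group 2	no	TTTCTTCTTTTTTAACTTCTATCCCA[C/T]TCATTATACCAAGATCAAACAATAA
rs2104286	group 3	yes	TAGATATAGTCATGGTAACACAAGTC[A/G]TATGTGGTAAGATCTACTGAGCATG
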