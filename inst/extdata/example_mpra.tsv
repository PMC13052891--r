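seq	barcode	ct_RNA	ct_DNA
CGGTGCGCCTTGTTGGTACTGAGCGGCACGATGGCGCTCTGTCAGCGAGTATAACTAGAGCTCATCGTCCCGGTCGAGCGAATTCGTTTCCTACCATCAGAATCTCTAAGATATGCAAAAGTTCACATAGACTGGTTATCTTACTCAGCAGGGCGTCCTA	CAGAGGCTTGGGCGCC	684	17
CGGTGCGCCTTGTTGGTACTGAGCGGCACGATGGCGCTCTGTCAGCGAGTATAACTAGAGCTCATCGTCCCGGTCGAGCGAATTCGTTTCCTACCATCAGAATCTCTAAGATATGCAAAAGTTCACATAGACTGGTTATCTTACTCAGCAGGGCGTCCTA	AGAAGAACGCGCGTGC	575	17
CGGTGCGCCTTGTGCGTGCTGTTCTGCGCGATGCAGCGCAGTTAGCTAGAATAACTAGAGCGCATCGTCCCTGTCGATCGTATTCGTTTCACACCATCTGAATCTCTTAGATGTGCAAATGTTCACATAAACTCGTTGTTTTACCCAGCATGTCGTCCTA	ACGTCACGGACTTGCA	0	19
CGGTGCGCCTTGTGCGTGCTGTTCTGCGCGATGCAGCGCAGTTAGCTAGAATAACTAGAGCGCATCGTCCCTGTCGATCGTATTCGTTTCACACCATCTGAATCTCTTAGATGTGCAAATGTTCACATAAACTCGTTGTTTTACCCAGCATGTCGTCCTA	CCCTACTCTGAAGATG	0	22
CGATGCGCCTTGTTCGTACTATATGGCTCGATGCCGCTCTGTTAGCTAGAGTAACTACAGCCAATCGTCCATGTCGATTGAATGCGTTTCCAACGATCTGAATCTCTTAGATATGCAAATGTTCACATAGACTCGTCATCTTCCGCAGCAGGGCGTCCTA	GATTCATAACTGCCGC	0	15
CGATGCGCCTTGTTCGTACTATATGGCTCGATGCCGCTCTGTTAGCTAGAGTAACTACAGCCAATCGTCCATGTCGATTGAATGCGTTTCCAACGATCTGAATCTCTTAGATATGCAAATGTTCACATAGACTCGTCATCTTCCGCAGCAGGGCGTCCTA	TGACCCATGACGGACG	0	18
CGGTACGCCTTGTTGGTCCTTTTCGGCTCGATGCCGCTCTGATAGCTAGAAGAAATAGAGCAAATCGTCACTGTGGATCGAATTCGTTTCCTACCATCTGACCCTCTTAGATGTTCAAATGTTCACATAGACTCGTTATCTTACGCAGAAGGGCGTCCAA	TACGGGAATCGAGAAA	574	19
CGGTACGCCTTGTTGGTCCTTTTCGGCTCGATGCCGCTCTGATAGCTAGAAGAAATAGAGCAAATCGTCACTGTGGATCGAATTCGTTTCCTACCATCTGACCCTCTTAGATGTTCAAATGTTCACATAGACTCGTTATCTTACGCAGAAGGGCGTCCAA	TCTCGACGTATGAAGT	829	19
CCGTGAGCCTGGTTCGTGCTGCGCGGCTCGATGCCGGTGTGTTAGCTAGAATAACTAGTGCTTATCGTACATTTGGATCGGATTCGCTTCCTACCTTCTGAATCTCTTTGATGTGCAAATATTCACTTAGACTCGTTATCTTACGGAGCAAGTCGTCCTA	GTGTCGTCATAAGATT	0	26
CCGTGAGCCTGGTTCGTGCTGCGCGGCTCGATGCCGGTGTGTTAGCTAGAATAACTAGTGCTTATCGTACATTTGGATCGGATTCGCTTCCTACCTTCTGAATCTCTTTGATGTGCAAATATTCACTTAGACTCGTTATCTTACGGAGCAAGTCGTCCTA	GATTTGGTCTTAGAAT	0	18
CGGTGGGCCTCGTTCGTGCTGTTTGGCTCGATGCCGCTCTGTTAGCTAGAAACACTAGAGTTTCTCGTCCCTGTCTCTCGGAACAGTTTCCTCCCATCTGAATCTCTTAGACGTGCAAATGTTCACATAGACTCGTTATAATACGAATCAGGGCTTCCTC	TCAAGCGTTATCGGTC	0	27
CGGTGGGCCTCGTTCGTGCTGTTTGGCTCGATGCCGCTCTGTTAGCTAGAAACACTAGAGTTTCTCGTCCCTGTCTCTCGGAACAGTTTCCTCCCATCTGAATCTCTTAGACGTGCAAATGTTCACATAGACTCGTTATAATACGAATCAGGGCTTCCTC	CCGAGCTACTAATGGA	0	19
CGGTGCGGCTTCTTCGTGCTGTTCGGCTCGATGCCGCTCTGTTAGCTAGAATAACGATAGCTTATCGTCCCTGTCGATCGAATTGGTTTCCCACCATCTGTAAATCTTAGATTTGCAAATGTTCACGTAGACTCGCTATCTTAGGCAGCAGGGCGTCCTA	GCCGATCGGCGATCAT	1275	25
CGGTGCGGCTTCTTCGTGCTGTTCGGCTCGATGCCGCTCTGTTAGCTAGAATAACGATAGCTTATCGTCCCTGTCGATCGAATTGGTTTCCCACCATCTGTAAATCTTAGATTTGCAAATGTTCACGTAGACTCGCTATCTTAGGCAGCAGGGCGTCCTA	TTTAAGGTACAGCACA	1626	29
CGGTGCGCCTTGTTCGTGCTGTTCGGCTCGATCCCGCTCTGTTACCTAGAAGAACGTGAGCTTATAGTCCCTGTCGATCGTATTCGTATCCTACCATATGAATCACTTAGATGTGCATATGTTCCCATAGACTCGTTATCTTACGTAGCAGGGCGTCCTA	CCCGCTGAAGAGCCGA	1174	26
CGGTGCGCCTTGTTCGTGCTGTTCGGCTCGATCCCGCTCTGTTACCTAGAAGAACGTGAGCTTATAGTCCCTGTCGATCGTATTCGTATCCTACCATATGAATCACTTAGATGTGCATATGTTCCCATAGACTCGTTATCTTACGTAGCAGGGCGTCCTA	CTTCTACTATAATACG	1023	26
CGGTGCGCCATCCTCTTGCTGTTCGGCTCGATGCCGCTCTGTTAGCGAGATTTACTAGAGCTTATAGTCCCTGTCTATCGAATTCGTCTCCTACTATCTGAATCTCTTAGATGTGCAAATGATCACATAGACCAGTTATCTTGCGCAGCAGGGCGTTCTA	TCGCATCGAATTGAGA	1033	28
CGGTGCGCCATCCTCTTGCTGTTCGGCTCGATGCCGCTCTGTTAGCGAGATTTACTAGAGCTTATAGTCCCTGTCTATCGAATTCGTCTCCTACTATCTGAATCTCTTAGATGTGCAAATGATCACATAGACCAGTTATCTTGCGCAGCAGGGCGTTCTA	GGTCCGTGAAACGCAT	1941	24
CGGTGCGCCTTATTCTTACTGTTCAGCTCGATGCCGCTCTATTAGCTAGAATAACTAGAGCTTATCGTCCCTGTCGATCGAATTCGTTTCCAAACATCAGAATCTCTTTGATGTGCAAATGATCAAATAGACGCGTTATCCTACGCAGCAGGGCGTCCTA	AACAATTCCCAGTCCA	973	23
CGGTGCGCCTTATTCTTACTGTTCAGCTCGATGCCGCTCTATTAGCTAGAATAACTAGAGCTTATCGTCCCTGTCGATCGAATTCGTTTCCAAACATCAGAATCTCTTTGATGTGCAAATGATCAAATAGACGCGTTATCCTACGCAGCAGGGCGTCCTA	TGTTCCCATAAAGAAC	1441	16
CGGTCCGCCTTGTTGGGGCTGTTGGGCTCGATCGCGTTCTGTTCCCTAGTATAACTAGAGCTTGTCGTCCCTGACTATCGAATTCGTTACCTACCACCTGAATCTCTTAGACGTGCAAATGTTCACCTATGCTCGTTTTCTGACGCCGCAGGGGGTCTTA	CCGTAAACACCTGAGA	1271	25
CGGTCCGCCTTGTTGGGGCTGTTGGGCTCGATCGCGTTCTGTTCCCTAGTATAACTAGAGCTTGTCGTCCCTGACTATCGAATTCGTTACCTACCACCTGAATCTCTTAGACGTGCAAATGTTCACCTATGCTCGTTTTCTGACGCCGCAGGGGGTCTTA	ATGTAGCAAAAACCTC	756	17
TGGTGCGCCTTGTTCGTGCTGTTCGGCTGGATGCCGCTTTGTTAGCTGGAATCACTAGAGCTAATCGTCCCTGTCGTTCGAATTCATTTCCTACCATCTGGATCTCTTAGATGTGCAAATGTTCTCATGGACTCGTTATGTTACGCAGCAGGGCGTCCTC	GTAGATTGATGTGGGC	718	21
TGGTGCGCCTTGTTCGTGCTGTTCGGCTGGATGCCGCTTTGTTAGCTGGAATCACTAGAGCTAATCGTCCCTGTCGTTCGAATTCATTTCCTACCATCTGGATCTCTTAGATGTGCAAATGTTCTCATGGACTCGTTATGTTACGCAGCAGGGCGTCCTC	GTCACCTGCCCCAGGC	1454	26
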