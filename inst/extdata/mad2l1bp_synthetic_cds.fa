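>MAD2L1BP_synthetic
ATGACACGCCAATCGTGTCTAACTTTGCATGGTCCAGGAAACACTTCTCTGCTCCTCGGCGCGACGATCAAAACCCGCATTCGTAGTTGGAACATTTATAGCCTTTCATTCGAGAAGTGCACGTACCCTGCTCCGCTGTGTCTCCCGAGGAATGGTAGCGCATTGGGGGCGTTTCGTCTTTGTAGGATGAAAATACGGTCGAACGGGGTGGCATTCCATAATGGAATACAAACCAACTCCCTAATTGTTAGGAGTGTCCGCGAGCGCTGCCGAGTAGCAGTACAGTATGTCGCGTTGTCTCTGAAAGTGCGGTGCATATGCATTTGGGATCTTCACTTTGCTAACCTGCGAGCGAGATATCAAGAGGAAACACTGAGGGCCACGTTATCAACCGAAATTCTATTTGGATGGAAGGTGTATGTAAAATATTCTTCGAGCTTATCTACACCAGAATGCGTCTCCAAGTTCTCGAACGCTACCACGGTTGACCCCTCGACTCCCGCAAGACTTTTGTCATTCGCAAAGCTAAGCATTTCGTCGCGAACTGCGTCTTGGATAGGGCAACAGGCCGTAGATAGGCCGCGGCTACTGAGAGAAAATCTACAATACAGCGACCATGGGAGCACGTCAGCACCGGGAAAAAAACAGGTTTTCTACTTGTTTCAGGGGCGGGATCCTTTGAGCATAGAAAGCACCATATTACGAGCGATATTGCGGTATCGGCATGGGATCCCGCGTCAGTTGCGTTCGTCGTTCGTGCGGAGTTTGCAGACAGGATCCCAGTCTCTACCAAAAAGAAAAGGAAAGGCGTTTGGGCTGAGCTGCATATCGGCTGTACGCCATGCATTCACACGACACGAATCAAGAAGTAGGATGCCTGCCGCGTGTCTACAACTGCGTTCAGACGATCCTCCTATGTAA
>MAD2L1BP_synthetic.utr3
CCGATCATGATACACTGCAATTATTGAAGGGAGTCGCCTCTAAGTGCCGGTAAGAAGTTTCAGGATGGTCGTAGCGGGGGAGAGCCTCTAGTGGAAACGTCCTTGTCTATAAGCTTGCTCCAAACGACATAACCAAGGAGGGGTCCTCCGTCCAACAAAACTATACAAGCGATACAGCGACTTGTACGAACTAATAATAA
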