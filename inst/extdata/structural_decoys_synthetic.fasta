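>rRNA_decoy_1 synthetic
GATCGCGATCCATACGACAAAACGTATAGTTCATCGAGAACAATCACAAAGCCGCGAGCCAGTTTTCCCC
ATGCTTAATTGCTTAACTCCTGATCTATACCAGTTCGCGAGAGCAGTACGCTTACACTGGCTTCCACCCT
GTTGATTTAAAAAAAATCACACTGTCCGGTGATAACCTGGCCGGATAGCCTCCCTCTTCAAAACCTGGTG
ACCCGCAGCTCTCCTGCGGCGAGTTATGGCTGGTGTTACGAGTGGTCTGCAGTCGTGCTCAGGTGAATGT
GCGTCCCCTCCCCCGAGATCGCTATTGTAACTACGCGACTCTGGCTTTAACCGTTGTGTCGTATGCTGCG
CGAGAGGAAAAGATTGGGCTGTAGCGGGAGCCATAATGCTGGGCTACCTCCACACCAACGGCACAGCTAG
GACGGAACAATTTTAACACGTTCTATGAACAGGAGTTGCTGTGATCGGAGCTAAAGTCACCGTACCCTAG
AGGTCGCGACCTTGTGGCTCACCCCGCCCAACGGTGCATCTACTCGATGTCGTCGATTTTTACATGACTG
AGCGGAGCTGCGGCTGTCCGGGTGCCTCTGCTGCGCTGGTGGACACTGAAAAATCTAGTGTTCCGTCTCG
TCCTCATATATGCAAGGCCCAATGTCAGCGCAACTCGGCGTGGTAAGACTACGACTTATTAGTAACAACA
GGATTGTGAAACTTTAGGAAGTTCTTATTTCAAAGCTGGTCTGAGACGAAATAGTCCTACCTTATCAAGA
GTACTATAACGCGGTGATAAAGGGAGTTGCATTTGATGGACAGATAAGTGTGACACCGTTATTCTCAGGG
TCCTCTGTTAAAAGGCAATGCGTATTTAGTCTTAGGTATGAAGGCTTGTGAGGAGGGTCCTGGTGACATG
TCTCATAACGCAAAAACGTTGATTCCACACGACAACGCTGCAGTCCGCGCCGCGGGAACATAGGCTTGTT
TTATAATGACGGCTCGTGTAGGTTTATATCTGCCGCGTTAGGATCCTGTGCTAGGACGAGAGAGAGAACA
GAGGTCGTAGGTGCAACGCTACTTATTCTTTGGCCCACCGAGTCCCTAAGAAAAGTGAACACCTAGTATT
CATTAATTATTCAAAGCGTTGGGACACCTATAATTCAGTGACGCCTTTCGACACACATCTCATGGTGGGA
CTCGTGGTGT
>rRNA_decoy_2 synthetic
AAGTGGGTTCCCCCTATTTAACACTCGGGAGGAAGAGTTGGCAAATTGTGTTCCCTATGCGGCTACTACG
GAGCCACGTGTAGCACTGGGATGCTGGCGACCAATCCTGTCTATCCAGTGCATAACTCTTCATCTCAATG
ATAGTAGCGATATACTAAGGAAGAAAAGGTGCGCTATGTCGTAAAGGATCCATTTAAAAAGCCGAATTTA
TTCCCTAGAAAAAATAATGCGAAGTCGGTCGTAGATTCGCTTGTATTATGTTGTCGCGACCGAACCGACT
AGATCCAGATGGACCAGCTAGGCAAACGTTGTACTGCGACATGCCATGATGCACGGGTAAGCCCTACATA
TTGGTTCGCGCCTAGCTAAAAGCGAAAAACTCTTCCATAACGTCCTGCCCAAGTGTCGCCCCATTGTTGG
AGTACCATGTTGTGCTTGTGCGCCCACGAAAAGAATTGCCTGAGGAAACAGCACCTTAGTTTGTGATTAG
AGATTCCCTTCATGCGGGCTTTCATGGAGCTGTATTGATAGAAAGGGCTGTGAATCAGCTATCGTTAGGT
CCATTCTTCCATCATATCCAAAGTTCTACGACCGGGCCGT
>tRNA_decoy_1 synthetic
TCCGTAACTACCCTGCGGTAGCCAATCGTGGGGAGGCCTACATCGGCGTCTACCCCCTGCGTTGGTGATA
GGCAAGAGCCCTTCATTCCG
>tRNA_decoy_2 synthetic
ACCTCTCGGTACCCATAGTAAATGCTGCGGTGTTACATATAGCGGCGAGTCCGGGCGTCCCGGATCAGTG
TTAACCCGGGTGATG
>snRNA_decoy_1 synthetic
TACTTAAGTCTCGACTCTTCCCGGGTATCAAGAGACTAGTCGTCGAGTATGTATCGGGCGAGGCTTTTGC
CGATCCCTGGACACTAGCAATCGGGAAGCTCTTGCACGTTGGAAGAGGAAGCATCCTAGCCTTGTATCCA
AGAATCAAAG
>miRNA_decoy_1 synthetic
GCTCTAGAGGGTCGCGGTACGTACCGGCAACTGGCACTGTGCATCGGCTGGGCCGGACGCTCATCATGCA
>miRNA_decoy_2 synthetic
CCGCGTACCTCTGCTCCGGTAACTCAAGAGGGCTCGCCATTGAAATTAAGTTTCAAAAGTGGCTG
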