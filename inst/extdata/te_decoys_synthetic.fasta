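>TE_decoy_1 synthetic
AATGGGGACGACTAATAAAAATCCTCAGACCCGATCAAATAGGCGGTTCACGTTTTTTTGAGGCTATACA
TAGTTTAAGGAGGTCCTGGTTTGGGCCGCAGACGTCCAAAGGCTAAAGCACTCATGAATCATCATTTGTA
GGCATACATCTAAGACTTTTATTGTATTTTTCCCCGATGACACCCTTCAGCGACTAATGGCGCTAACCAG
TTTGCATGATGTCGTACATTAGCGAATGGTGCCTTATCGCCTTGAAGACTGAAAATACATGTGAGAATCG
GATAGTACCGAGAGCCTGCCGATCACCCCGGACGTATAGGCTAAGTTCCCTTCGCAAAACCGCCCGTCAT
TATCTCTAAATTAATTCGAATTCAGCCGAGTGTCTACCCACGACTATCAAACGTCTTTGCCCGGTCCACG
TGCTGTGAAGCAGAAGTAGTATCTATTGATGGGACAAGATTTCGACATACAACCATCTACTGCGCGGCCT
GCGCGTAAACGTATTATGCACGCACGATGCACTTGCAACTTAAATGGCTGACATTTAGCGGCCACTCATC
GATCTCAGAGGGGCGCGGTGACGATGGAAACACTGAGAGTGTCGTATAGTAGGATGCAACCCTTCTATCC
CGACCTGAACTTTGACCAACCCGCTGTTCCATTCCATCACATCCTGCAATTGACATTCCGCGCTGTCACG
ACCAAGGCGTCGTTCTGCTGTAGTCCTGCGGTAATGTGTTGATGCGTCAGATCCAGAATTATAGTACAAG
TATTCAGCAATGCGCGACAGGAGCTCCTTTGAGTGTACCAATCCGTCTTGTACTTCCTCAGATCGCCGAA
CGCCTGATCTCCGGGCTCCATTAACTGGGGTCGCGCTTCATTATTACGTGGTTACTTATA
>TE_decoy_2 synthetic
TATTGGGAGCAGAAACCTCATACATCTACTACTGCCGTCCATTTCTACAATAGGACTGGGGTAGCCAGTT
TTTCTAGGTAAAGACAAGGTCAATGAGCTCGTACCTCTGCCAGACAGGTCGAGATGGTCGGCACCTTTGC
GATCCCGAAGCCAATATGCCGCCTCACGACAACGGATTGGCACGCGTACGGAAGGAAGCTAGCCCGTTAA
TCTGCTTAGCTTGGCCCAACCGCTAACTGTTTCACGGGCCGTGACAGCTTACCAAATTGGAAACCTCTGG
AGCGCGTGTGGCCTGCACGAGCTGCAGCGATGCGGCCCTGACCGAAACGCAACCGTCCTCAGACTATGTC
CGGAGATTAAGGGTGCTGGTACCAATTCCGGTATGGCAAGCGTAAAAGGAATCGTCTGTTAGGTCGGCGG
CTGCCCTAAAAGTTATCAACTGTAGACCAGGAGTACAGTGGTTGCGATGGAAGACGCCAGCCAACTGTCT
CTTCTACTTCAGTCTAGAGATGCGAACGCACTAAATTTCCGGAAGCGACTTGTGACATCGCCTCCACAAA
TCTCCTAACTGAACGGCTAGCGTCAATTTTTATGATCGTGTTAGAATTAGGGTTTGCAGGTCCACAGGCG
AAATAGTACTATTCCGATTGGTGCCTGCTGGCGCCGAAGGCCTCACGGACGTCGCAGCTTTATCTGCGCA
>TE_decoy_3 synthetic
AAACCAGTGTAGCGTACGATCAGAAGAAACAGCGGTTATTTGTTTAGACCCAGGTCGGACAGCCGTCCAT
GCTTTACGTACGGTATTAAGCCCCAAACTCGGCCAAGAAAGGTTAGCCTGATCGGAGCAGTTGGCACTGA
GCTTTTTTCCGCGAGTATGACTCCGCCTACCTTGAGACTTGCTAGCTATACGGGCCATTAACCGGTCACA
CGGGTCTCTACCTGGAGGAAATTTAAAAGATGGACCCATCCCTAGAAACCATGTTCTGTTCTAAGCCCTG
TGACCCAGTGAAATGACGGACAATCTTCCTGACGCCGCTACCAACCCTCTGCCAATACACCCCGCGAACC
ACAATAAGTGCATAAGGGGTTTAGGCCTGCCTAAACGGGGTCGATTATCGCGAAGACGGAGTCGGTCGGC
TCAACGCCCTGCGATCACTTCAACGATCTCATGGACATAATGAGAACTCCTCTATAAGGTTATACGCGAG
CCACACCTTT
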