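>dw1_recessive_amplicon
TGGCGGTCCAACGTCTAATCCCCCGGACTCACTGTAGTCACAAACATGAGCCAACAACTCGAGAAAGAGT
TAGTCGCGTATTGGGACTCCTATTCCCGAGTCGTGCGTAGTATAAAAGCAGAGATAGTATCCCTAACGAG
ATGAAGTATCATACATGGAGGACATCGTTAGCTGTTGTTAGGATAACCAGTCATTCGGATTAGCTTTGCG
ACGAGAATAGTCGTGCCTTCCTGTCTTTTATAGGATCAAGCGCCGGGCGGTCATGTCTTTTGTAGGTTTG
GCTCACTCCACAGGTGAACAGCGGTGAACATTTTACCATTTTCTACTCCCGCAGTCATCATGCCCAGCTT
GGGTGCGACGTCGGACTCGGCCTACATCCTTGGGCCTCTACACATCCTCTACAAGCGCAGACACGCCATA
CTTCAGG
>dw2_recessive_amplicon
CAGTTCAAATCAACGAGGAGGCATTAAGACGAGATGAGGGGGCTCACAAGTATCTCCGCTATTAATAAAA
CTCAAGCCACGTTGACCCCGGGCGCATCTCGGACCCTCCATTGGGTGTCCTGGAAGAACCGGAGTCTACA
ATAAACCTCCTCGTTCTTGGTTGACCCTCTATTGGTGTGCATCTGCAGGAGGTAAGGCCTGAACGTACTA
CCAAGGCATCATCAATGGTAGATCACGCCCCGCAAACCGTATTCCTTCATAGAGATTTCGAAACCCGGTC
ATGTGATAAAACTGGCTAATTTACACACACCCAGCAACGCGCAGAAACCCGTGCTAAATCGCTAGTAAGC
CTGCACGCGAGCCTGGTTGTCCAAGGGACCGACTCCAACCTGATGAAATGGTTTCGAATGACTAGCGGAT
GGTGACCATGCGAGGGGTTATCCGCCCGGTCGGAGGTTGAGCCGATCCTCCCAAGCATCTGTGCTGAATG
TGCTGTAACTGCCAAGGGTTTTCAGTTTTCTGGGATCGCCTCGAGATTACCCCTGCTTGGCTGCACGGCC
GGTTTCTACGGGCTTCGCCATTTGAGTTAAAATCGTCCACACATCACGTCCTTCGAAAACATCTACCCTA
CGCCAACGTGATTTATAGTTCGAGGAGAAGGAATAGCAACACAAAAAATACTTACCGATTCAAATTCGCC
CGTACAAGTGGCGGCGCAGTGGAAGCCAGCTGCGTTGGCAGAGTCCAACAAGCGTGTCCCTCCTGTACCA
CGGGTGCATACGGTCAGCGATCACTTATGAAGGATACCAGACATGAGCCGTCGAAATTCGAGAATGTAAG
AGTTTCAGTCGAGTTTTGGGCAAGACAATATAGACCGCTATCATACTCAGTAAGGAAGATAAATTGAAGC
TTTTCGTCTCCTTTTTGTCATGAAGCAGGTCTCTCATTTTAGGGGAGAACGGAGGAGCGAGCGCCTATTC
TCATTTCACGACGGA
>dw3_recessive_amplicon
CGTCATCGTCCAGAACTCGGGTCTACTGAATAAGTACATAATGAAACTGTGATACCATATTGGCTAAGGA
GCTTAGAGATAGGCCGGCACGCGCGGTTCAACTGCACGGGCGAATGTGTTGAGCGGATGGACAGTACCAT
AGCAGCTAATACTGTGCGTAGGTACTAACCATGCTGACACTAGGTGGTAGGAGTGTGTTGAAACTTCCGC
CAACCGCCGTTCCACGCTCGCAGGGACATCGTGAGCGTACAGATTCCGATCCAGGCAGAAGTCATCGCCC
AACTACCGCTGGCCCATCGATAGGCCGTTAGACTCTACTACCGGTCTGGAGCTAATGCCGTTGGGAAGAG
GACTACTCACTCGAACATAACGGGTACGGGTGCCCCTTTGTATATGCGGCGGTGGGTTACTTACGCAAAG
GACCAACCTCTCAACTATGCGGCCGAAGAGAGTGATTTTTAGATCGTATCGAGAAATAATATCAGCGTAA
CATCTAAACGACAGAGCGTGTGGGAATCGACTTCTATAGCCACACTACCTTATCAGGTCATGTCACTAAG
TCTGTCGTCGAGAATTGGGGCTCGGAGGTTGCGTCTCAGCGTAATTTGATATTGGGTTCGTCTGTCAAAG
CCGGACGTTAACTGTCTCCGTTGACGCGGACTGGACTTCTTCTGACTGTCCGGGTGGAACGATGACGCCA
TTTGCGGTGCAATCGATGATCTAGGCCCGGTATCGCGCATGCTCTGTCTTAACCAGGCGGTGCCAACTCA
GCAAATGAGGCATGCCAAGATCGAGACAGAGTAGTGCATCGCTCTTGTATCACTAGCCGCGTGACAACCG
GAAGGGAATCGTACCATTTGGTCGTTGTATGGAGATGTGTACTCCCAAGGTTGATCCCAGTGCGTACCTT
TAAAGTAGTCAAAGTAAAGTGGACATGACCGCTCACTAAAAAACGACAGCCTGACTATACGTAGGGTCAT
GTAGGTCTCAGAACCGTAGAATGTTAACCGTCTCTCGATTTCAGTTAAGCGGGTGAATAGCACCGTACAC
TCGGCCAAAAAGCGGACAAATTACTGCTATGACCGCGCTCGATATACCCAAAGGCAAGTGTACCTCGGCT
CAAGCTTAGCGATGGTTTTTGTACACTGTTTCGGGGAACCCTTACCGGAAACTACTAGACTGGCCCCCTA
AACACCAAAAGGAGTGGGAGTGCCTGGGGGAATATCCCGATGCAGACAAAAAAAAGGTGGTGGAGCAAGG
GTC
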