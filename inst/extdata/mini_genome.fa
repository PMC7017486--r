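>chrF
CCTTCGGTAAAGACGGTTGTAACAACCGCACGGGCTACGTTAACTTAAGGAGTACCCGTATTCACGCTTTCGCATTTAAA
AACAGTCATATCCTACGTCAGCGCGACCTTGTCGTGGAGCACTGTATAGCGAGTCCGATTTTTTAAAGGGCGGCGTTGGT
TTGATCGGTGAGTCCCGGTAGATTGGGGTCACACAACCCGTCGTTGCGGACTGTCCTGCCGTCGGTCTCAGAGACATACG
ATCGTATCAACAAGCGAGAGGCGAAAAATTAGTTGATTATCTGTATGCTATGTGGCAAGTCGTACCGAGCCACCCTCGCA
AGGCTGTGTCGAAGGTTAAAGACTACATTCCCTAGCGGGACCATAGATAGGAGGGAGGACATGACAAGTAGCCAAGTTCA
ATTTAACATGCCCCGATGGTGGGCGCGAGGCTAATATCTCAGGGCTACTGCTGGATCCAAAGAGAGTATGTTCTACGTGA
CGATAGTTTTTGAAACATTAAAAAGCGTCATTGAAGTAGCTGACTTTAAGGGGAACATAACTAGAGCGCGATTCTTTATA
AGTGGGTACTTGAGCCCGCGTAGGCCATTAATGAGCAGCTGAATTGACTGAATGCCTCACGAATCAGCGCGGCCTTTGTT
CTAAATAGACCAGTAGGGAGCGGCCGTTTCCCAATGTGTTACTTTCTACTCTAAGCTTCTCATGAAAGATAACAAAGTGT
CGCCACTGCTCGGCCTGTGATTGACGTAGCTCGTGTAAGAGCTTTTCGTGCGTGCAGCGAGGGACCGGTCCCCAGTTATT
TCACCGATACCAGCCTCGCTGAGCCTTTGACACAAGGTTCCACTAGTCGTGAAACCGAATGACCAAAGAAGAATATGTAC
TCTCGGTGCTCACGTGCTACATGCCGCGTCAAGATTACTGATTCTTGTCTCACAGAGACCGCGACAGACAGCACCGCCGT
GCATCAAGCAGGTGTGAAGGCCCCCTAAACGTCCTTAAGGCAGAAAGTTGGGTCATCTCCGCAGATGAGTCCTTTCATAC
TCTATACTAGTAATGCCGACTTTGCCAGACAACCAACCGACACATTTAGAAAAGTCCGCCTTATTGAAATTTGGGGAGAG
GGCCCTCCGAACCTAGGGCGAGTTGTGTAGCGGGAATTCAGAATTCACCAGTGCCGCTGTTGAATGCGCGAGACACGTAT
TAATCCACGGATGTGCGGCAGAATTACAGTGCTCCTAGAGGGAAAGCCGATCGGACTTTTAGTAGAAGAGTGGTTATTCA
ACAGGTTTAAGCATTCGCCGGCAGACTATTGTTCGGTTTTCTTACGGAGGTGTGCGTTGGCGCTTCCTTGGATGAGTACA
TCAGCAAGCGACTTGAGAACCATGCTGGTTGTGCCGGACCGATCATGGGTCTCTGCTCGAGAGATGACCTTATTCAATCG
GGCAACACCGATTGCGTTTGGAACGAAAGCTCCCGGTCACATGAACATCCATACTGATACTACGAAGATTATTTTCTAGT
AGTTAAGAGATACGGTCGTAAGTACTGAGTACAACAATCTATAAATGATGCATCCATCAGGAAATGGAGGTATACACCCG
TATGCGACGGTTAATCGTCAAACGAGGTACCTCCACCTACATCCTCACAGACTGCGCCCAACCATTGAGACAAGAGATGG
CACGTTCATCGAGCGGTGCGCCTGGTACTGACAATCATCACTGGCACACTTATGCCAGAATATTATGTAAAACAACAAGA
ACCAATCGCGGTTGTATTCCCATGAGCCTCGAGGACCGAAGTGGTAATCAACTTACTATATCCACTCTGACGTATGTCAA
CAGTAACGGGCTGGGGTGAAACTGGCTCAGAGGGTTTTAAAGGCGTGAAGGCCTGCCGATGGGACTCAGGAGCTAGTATA
CGTATAGTGCTAGAATAAAAAACATCTTCCCTCACAGCTTGCTTCGCTTATTAAAAGTGATAAACGTTCAACATCATGAC
TGGCTCCATATGAGCCTTCGCGACATTGGTTCGACTCTTACCTATGCCATGTCATATGGAGTATTCCGTCCACCCTATAA
TGGTTGGGGAGTGGTCTTTCACAGGGTACTGGTGCGCTGCGAAGATGACGATCGCTGCACCTGAGTATACATCTAGATAC
AGACGTGGCTCCCCCGTAGGACCCATCGCGTCGAGGAGCTAGCTTGCTAAGGGAAATACAACGGTTCCGTCTGCAGGGGC
GCCCTAGGGTCTATAAAGTTGCCAGCGATAGGGAAACTAGTATCGGTCGCGAGTTACCTGAGAGTCCACGAGGGCTCTTG
CCTCATATCCCCTAAGAGAGCGTCTTTGCCAGCGCTCTTACTGCCGTCGCCTCGTTCTGCGCATCTCACTAATATATGCC
ACATTCATCTATCTAGAGATTCTCAATGCACTCAATTAAGCATACTTAGCTGCGCGCACTATCCGCGGAGCACGATACAG
TTTAAAACTAGGAGTCAGCGATACTTGACACATTACCTTATACTGTCACCAAATGTAATATGGACTTTCCGACACTTCTC
TATTGGGTCTGATACCCTCACCAGGCATTATCATTAGGTCTGGGCGCGCATTCAGAGAGCCGGACCTGCATAGCTCCACA
ATTGCCATGATCACGCGACCTCTAGGTTTCCAAGGAGGACGTGTTTCCAAGTCGGGGTGCTTGGTGCGCCAGGGAGCAAC
AACGGTAACTGCGCCGGAGTTTAGAAAATATATTCAGAGACAGTCCCCCAAAGTGTACGGGCCTAAAAGATATTTGATGA
GCCGGTATTTCAAATATATTAGAAGCAGTTTTCACTCATCGCGCACGACGGAAGGGTCTATGCCTATTTACAACAACGGT
GAAGGCACCACTAAAGCAACAATATAGATGGCAACTCGTAATGTGCCTCGACCTGGTAGCCTATGAGTAAGCAGCTTACA
AGGATTATTGCAACGCCGAGTATTCTATTACAGAGCAAAGGAACTTTGGAAACTATCCTGCATAAGCAACTAGTTAAAAC
GACGAGCCCTTCGTGGTTGCGTCCGGGGATATCGCATATAATAAAATTGAGCCTGTGTTTGGTGCGCGAGAGGTACTGAT
ATCACATTTGCCTAACAACGACGTTCTTGTGGTACCATGACACACATAATGGGAACGTTAAGTTCAGGACGTCTTTACCT
CTCATGGGCTGTTGTGCGTACGTGCCGGAAGCTGATAACAGTCAAGCGAACTATGGTACACGACAACGTCTTTTTGCGTC
AGCTTAACTGGTTTAGGTCATACTAGGGCAGCTCTGTTGTCTTTGATCGCAAACATTGGGATCCTCTTAATGGGATAAAA
TCGAATATGCACCGACATCCCGGGTATCACTCGCGGATCCCAGTTTTTAGACTTCGTAGTGCATGCCCTATCCTCGCCAT
TCTTGTTTGTAGTTTTTCCGGTCGATGAATACGAGAAGATGGGGCACATGTCGAATTAGAATGCTTTCCCTCTGTGTTGG
TGCCTCAGAGTCTCGTTTCTTATAAGGCCGGAAACAGAGGATCCTTTTTTGGCGTCCTCGCGAAGGTATTTCTCCAGTCT
GAATGATCCCAAATTGGGGGCAGATTGCCCGGTCCACTGTGACGGGGTGTCGCCAAATGATTTCACGGGGACCTTTATCT
AGCCAGGTGAGGGCTAGTTCCTACACACTATTTAGGCGGTTTACAACCTGAGACTCCTCGCTCACCGGCTCTCAGTGAGG
CTTTAGGTGCCCCCTGAATGAGGATTTTCCCTCCCGCCCTTGGTCCATCCCAATTTAGGGAGACTGAAAAGATGGAACTG
CTGACTGGTGAGGGCCTTTTTCACCGCACTGCAGATCGTACTAAACGGTAAATGTTTTTCCTGAGATCGCGCGACGTAGG
TACCCACAATAACGTTTAAGCATGTAGACGAACTACAGGGTTACCATAGAGGTATGTCCCCTACGCACCCGAAGAATCGA
TGCACCGTAACGAACACATCCGACACATCGACGGAAAGAATATCATGTATCTGGATAGCCCCAGGGCGCAGTTGACGGGA
CTAAGAAACAAGTTCGACATGGTTACGTATTCTTGGAGTTCCTATGTCGCTGCTGCACCTTCAAAGTCAAGATTCGCCAC
ATCCTTTCGCCTTCGTACGGGATATTTAGGCACTGAACTAGGCACGAGAAATTGAGTCTTGCATTTTGCGTCCCTAACAA
GCAACTTGCAGTGCACTGGGTTCTCTTCGACAACTCCCACGTACACACGAGCACCGCCCAAGAGGCTATCTCCCCGTACG
CCATAACGCCAGCGTCAGGTATGGGTGCACCCTATATAGCCATTTGTATTGGGTAAGTACACTCTGAACAGCATCTTCTG
GGGCGCAGCACACCTGCATCGGACACGCTCTGTTAGCGGCCGTTGAAATCTTTAATGACACAGCCATGTTGACCCCTATC
CCGACTCTTGTACAAGGACTTTTTTTATCCTCTCCGCAGGTGTTAGCCGAAGCCATCTGGTCGGCCCTTGGAGGTAACGC
GAGCAGGGGGAAGGGGTATACACTGAATGAAACCTAATCTGTGGGTACGGGCCCGTTCACGCACAAGTGTAAGCCCCCAT
CTCCCGGGAGTACTTCTTCCGGCTGGGGCCGTTTAGTCGGTAGGAAGGCGTAATGGCATTACGAACGCAGAGGGCGTGGC
GGCCCCAATTCAGGTGCTTTCTCGCAGCGTAGGCCCTGCGTACCACTGAATCGATACCGGCAGGGGTTTTTGGAACCTGT
TGGTGGACTATTTGTGACTAACGACAGGGACCACAGGAGGGAAGGTCGTCACCGCCTTTTTCCAAGGCATCAACCTGTAA
CATTGTGCTGCCGTAGCATCTACACGCCCCTATCTTTGGATGTGTACCTGCTGGGTCTCACGTTCGGGTCGAATTGTGAG
CACGAAACGCAGATTTCTTGCCTCGTCTAACGATGGTATGGCGTTTACGCTACTGGGGGATAAAACGTGTCTTCTACACT
CAGCAGTGTAACCTTTCAGAGGGAGCCTGTAAGCGAGCGGGGATACTTTCTTCCTTGGGGCAGCGTATTGAGTTCGGACC
GTGTATACTTGCCGTAATTCACCTCGGGTTTAAGGAATTCCGCATTTAGTATATGTATAAGCAACTCGACCCTGGAGAAT
ATTCCTGCCACATTTGTGGCAAGAGAGCCTAAGCGTGGATGGAATACACCTGCTCGTAGCTGATTCTTTCGCCTGATGCA
TCAATGAAGACCCGAAATTCCTTAGGTCCCACTTGACGCCTTTGGAGACAAAGCTTCGGCGTCGACGCATCTCCAAATCC
TGTTCCTGGCTGAGGAGTATGAATGATCATGCATCACGTGCCACCCACATGGACGCGTTAGAGGAGTATGGTGTGCATGG
TAGCGCCAATCGGTTTTGCATGATACATTAAGACTATTATGTGTCTTACCGACAATCATCTAGTGTTGGAGGTAGAGGTT
AGAATGACAGCTCTAGTGGACACAGACGCCCCCGTTTGCTCTATGACTACCATGTAATGGGGTAAACACTAATCGAGACC
GCAGCTAGCGTAGAGCTCGATTAGAGAACATAAAATGAGATCAAAACCGCACGGATGGCTTTACGGCTTATGATTCCCCG
TTATAATAACGAGCCGGCGTCCTGGTATTATAACCGGTTAAGCTGCTGGAAACTTTATACTGCCATCGGTTTAACTGGAC
CTGGACATGTAATTCTGACTGTTAGTACTCTTAGCACTAATTCGTAAGACGAATGTTTCTGAGGTCAACCTCGCCTAGTC
GATCACAGATTTTAGGGTTATAATCGATCAAGAAAAGTTGGGATCCAATTGCTTCACCTTACGGGCTGATGCTTAGAATA
AAGACTGGTGGTTAACAGCACGAATGGATGCCATCATAACTTGATCAAGAGTTTCCGGTTATCTTGAGATGGAGCGACCG
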