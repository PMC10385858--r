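>low-AT3_01
GAATACCCTGCCAAAGCGTTGGTTGGATATAAACATGCTTACTCTTGCACTAGGTACTCTCTGAAAACATTTTGTTACCA
ATACCCCCAGTGCGTATGCCATGTGGTTACCTTTCTTTTCTTAACATCAATAATTACCCAAGACCTTGCAGACGGGCACG
AAGATGATATCAAGGTTGAGAGATGTGACCAGACAGAATGCCGTGATCCCCAGGTCAACCAGGACGCGGGGGAGTCTTCG
CACACTGAGCAGCGTAAAACTTTTGAAAATGAATATACACCCTCAACCCACGAGCGAGTAACAAACTGTAGCGGAAAATT
TTGCAGTGTATCCCTTAACTTCAATCAAACTTTTCACACAAGGTGCTGCCATCTACACAAGAAAAAAGTACCTGATTATA
CAAGTGTACCAATTCGCAAGGCTGTAGAAGAACTTCACCATCTATTTGGGGGTCCACAGCACAAGCATATTGATTGTAAA
TGTGCGCACTCAGGCTTCTATCAGCTTCAGGGAGTCGGGGAGTACGCGACAACGGTAGCCTGTCATGGCAAGCCCCATCG
TCTTTTGATAACTGAGTTTAGTTGTGTATTTGTCATCTCATGTAAAAAGTGTCATAAGCCATTTGAAACTTCGTTTCGTT
TGTTAATCACACTCCTCCAGGAAAATATCAAGAGTAAGGAATATTTCCCGAACTTTTACGGAGAGGCAGCAATATTCCAC
ATCCCTGCCAATTTCAAATTCTTTGACTTGCGTAGTGACGTATGCTTTGAATGCTACCTGATTATCTGTTCAGCAAATTA
TCTAGGTCATTATTTTTACCATTGTCATGAACATGACTCTCAAATTGGCTACTATAATATCAATTTTAAAAAATTTCGCC
AGAAGGCTGATTTTTATAGTGCTGATTGCGACTACAGGCATTTAGATGAGAATCATGTCACTTGTTGCGATAACCGGGGA
GTTATCGAGAGCCCGCTCTTATCATGTCGTAGGTGTGAGTTAGATAACCACAATCCTCGGAGGCATATATACGCTTGTGA
CCATTACCTTTGCTATTCATTCCGCTGTCCGGATGGCGACTTTCAGGTCTGTCCTGTCGATGCAGCAGACCACCCAAGTA
AAAAATTCCAGGGGCATTGCTTCCCAGTTCGCAAAGAAACCGTGTTTCGGAATAATAGTAAGAATAACGTTATCAACAAT
GTTCATCTCGCGTTGCTTTACTCACAACTGAGCAACCTAACCACTGACTGCATCGCAGTGCACAAGGTTAATAACGAGGA
TAGTGTCGGCCTGGATTACATTTTTCGAACGTATTGCAGATATTGTAAGGGTGAATTCAACTTGTTTGATCGGCACTACC
ATTATGTTCCTAGGGTATATAATGACCAACACGAACTGACTAATGACGCAGACCTCACTGAGTTTGAAGGGCACTGCGCA
CGTAATCCGTTGCCTAAGCATCAACCCAATCAACTGTGTAATGAGGACCACAAGCCGTATTAA
>low-AT3_02
ATAGCTGTTGTTGACCGGGAGCCGCGTATTCCCGACCAACTTACTCATACAATACAGGGAGTGACTAACTTTTACAGTCG
ACGTTCGAGCGGTCAACAGTGTTTTTATTACCAGCATGGTGAGTCGACACAGCATTTTAGCTACCCACTTCCCCCACAAG
CCTCTTACGATTATTTAGTGACATTTCAGCTTGCCGCAGAAACATGTTCGAATTTCGAAGATGTGATTGTTGAGGTCACG
AACCTCACATATGTATTCGATATTTCGACTATAGAATCAACAGTGACATGCTGCTACCACTTAAGTAATCTATCCTCCAA
CGAGCTCTTTCTGAACATTATTACTGAGAATCAGGGATATCCGAAAATAAATCAGGGTGAAGGATGCCTGGGGTACATCG
TGCACATCGATTATGCAGTTGCCATCAGTAAAACCAAACAAGGGGCTTTGGCTGTCAACGAGCCAGATCATCCTCTACCC
TACACCTATGGAAACCCTAGACATTACGTTTCTATTGTGATTAAGTTCAACTTTTGTTGTTCTTCAAATAAGGTAAAGTA
CTTCCAAAGAGATAAGTTAGTATTCCCAACCCATTCCGACAGTGCCCTAGCTACAGATTTCATTTTGACTCTTGACTTTT
CACACTTCCAAAATTTCTCTCAAGTAGCCACTGAACCGCAGCCTTTCTATCTTATACTATATACTTGTTGTGTGGATTAT
AACATAGGTTGTAAATACGACGTCTTTGCTTGCGCCATATTTCACCATCACAAATCGCACTCTAATCCCAAACATAATCC
ACTTCCCACTGACTTACAAAGCGGATTCCAACTAAAAAGCGCCACTCTTGACGGGAATGGTTGTGACTATCATTATTTGC
AGAAGGGAGAAAAGCGAAACGGGTATTCCCTATGTGCTAACTTGCAGCAAAACTACAACTCGTACATAAGTAGAGAAACT
AACATAACGTTACCCTATAAATACATCCTTGCAGCCCCGTCAGAGCCTGATCCCTCGAAGAGTAATGAATGCGACCACTA
TACAACTAACTTGACGTATCGCAAATATGAAACTGAAGAACAAGAAGCATATTATGAGTGCGGACTTGATTTCTCCTTAA
AATGCCAAGAACACACGAGGCAGTTGTCGGCGTGCTCACGAGCTCCTCAGCAATATGATCAACAGTTTGTATATCAAAAT
GTGTCTTGTCATAAATATTATAATGATTATATTACCGCATATCAACACAATACTGCAGGCCAGTCCCGCTATGCGGTGCT
TTGTAAGTTCGGTAGTGAATGTACGCTAAGTGACGGGATCAAAAGATATTTCGACTTCGTTCGTAGATTAGATCATACAC
CCGTAGAAGGCCATTGCCAAAACCACTTTGGAATCGAAAACGCGAGGCTTAGCATACACCGGAATTATCAAGGTGCACGA
AATAATAGGGAGCATGACATACAGAGCATTAATCACGGTAAAAATTCTGGATGTCATGAATAA
>high-AT3_01
ACTCAGGCACTGAAAGAAGTAATTTTAAACGCCGGAGATAGCGTTGTCACCTATAAATGTAATCGACAAAGACAACTAGG
ATATCATGAGTGCGCTCATTCGTACTTTCCAGGAACCAAATTTCAAATCGTACAAGTTATTTATGCTGCGGAAACTACAC
CGACCCAACTTGTTGGTGATGATGGCACCCAAACTGGCCATCAAGCCATATTTAATTTCGTTCCGGGACACAATGCAGCA
CATCCATACAATCAGCGAGGAGATCCGCCTGCTGAGTGTTATGAGCTAAATGGTAACGGCCAGTGTCCTAAAAAATACCA
TCCTGCGGCATTTCAGAATCAGTCTGGATATGACTATCTAGATTCTGTATTACTTCCGTATACATGTCATAGTGATGTTG
TTACACAATGTAACCGACCTCAATATTCACAATCTGGACATTATTCAGATTTAGATCACAGTTCCTGTAATTTTAAAGCA
GATTATATTCATGCCGCACTGTATCAGAAATCACTTACAATAAAGGAATACTCTTTTGAAGCACATACAGCACCCCAAAA
AATCAATGAACGTGCGTTTTACCATCTGCGAGACTTTGAACCAGACGCGAAGGAGAGAGAGAGTACAAAGAAAGACGAAT
ATCCTGCCCGGAATTGCAATATTGATTTCCGACCAAAAGATCCAAGCACTCATCATGCAAATAATACCGTTGCTGTTGAG
GTTGTAAATTATCTCGCGTTGTCTCTTGAAAAAAAACTTCCGGTTCAAGCAGGAGGGGAAGATCTTTATCACTTTGTTGG
AGCGGAATATTGTGCACTAAGTAAGAAGCAATCAGAGGGCAATTGCCCAGACCTTTGTTGTAAGGCTGCAGAAGTCTCTG
CTAATGGAGCAGTAGTTAATGGACAATTTCGGCTCCTTGAAGGAATCACAAATACAGTAAAGCAGCGTAAACAACTTACA
TTCGATTTACATTTTCAGCAAGAAAATAGAGCAACCGATGTACTTATCACTGGGCGCTATAAACAAACCAAATATCAAGA
ATGTGAGTACGAACAAAAAGTTTTTGGTTGCGATCAACCCAGTCCGGATAATTGCCATGGTCCAAAAATTCATAAATGTC
CATTACGTGCGTTAAAATGCCGATTCGCTTGTAATCATTTTACCAAGACTGGTTGTAATGCCCACTATGACACGGCACAC
TGTTACCGGGCAATATCAGTAGAAAAACAAGATGTTGAAGGTCATACTGGGGCATTGGCAGCGAAGCCGTGTGTTAATGA
TGTAGCATCAAATTTAGCAGCACTGGCTGGTGCGAGTTGTCAGATATTTCAGTTGTGTGCTCATCAAGAGACTTGTGAAA
AGTCAGATCAGAATCCACACCATACACGACATAAATATCAATTAAACAAACATTTACGAAAACCTACAGTGCCTCAGCAC
AATAATGATGTTCCGACACTTGAGCAAACGGATCAAAGATTCTTTAAGCTCACCCTCATATAA
>high-AT3_02
GAAACGTTTACTGATGCAGACCAGGATATCAATTACTCCAGAAGAGCATCTGTTTGTCCTGTAAGTCACCGGGATTTAAT
AAGAATTCTCCTGTATGACGAACCGAAAGGTATCAAAGGACCAAATGAAACCCGACCTCCCGCTGCTAACCAAGATAGTT
GTGGTAGACATCGGACGCTTTTTCTAACGGAATTTAGTAACACGTCACCAGATATTAACCGAATACGCCTTAAATTTAGA
ATAGGGGGGCGAATTATCTCTACACCTATTAAATCAGTAAAAGATGATAATTGTACCGAAAAAGAAAATGGGTTACAAGT
ATATTATAAAACACAGCATGAGTTAACCCTACATGAAGTCTACGGTCTAGATGACACCAATGCGGTTCGTCGGCATCGTG
ATGAAGGAGAAGATCAGAATACACTTTTAGCAATCCATACTTGTATTCCGATTGAAGATCATAGGGAGGATATCGTATGT
TATGCTCTCCCTAGACTGTATACTATTTGTACCACCCGCGATTTCGAGAAAGTGCAAAAACGGTTCAATTTAAGCACGGT
TGCGCATCGGGGTATTCGATTTTTCTTTAATCTTTACGAAAAGCAGGACAAAAAACAAAATTACGCATATCAATTTTTTT
GTCAACCCCATGATGCAACTCGTCATTTAAGCTTTACAGCACTCTACTCACCCGAAGCTCAGGAACTTTGCGGAATAAAT
CTCCGCTACCCTTGTGATCATGTCTATGTTATTTGCATTTTTCGAAATTTCACACCACTACAAGTAGACGGAGCTTGCAT
TAACAGTGTTTTGGCACAATTTGCCGATCAAGAAATCTTTTGCTTTGTTCATCCCGATTGTCAAGACGGCGTATACCAAA
TCGTGGTAAATCAATATTATGAACCAATTACTATCGTAAAACTCGACCCAAAATTTGACGAATGCAAACTTAGCCAATTC
ACTCGACATATTGAAATTGGTACACTCGAGTGTGGCCCTCGACTTCCTGGAACTCGGGAACTAACGAGGCTCTACGAAAA
AGTAAACCAACAAGATCAAAGTCCTACCCGATCCTACCAGTCTAATCGACAGACATGTAATCCTCGTTGCCGCACTGGAC
GTGATTGTCCATGTCAAATTGCTTCACTTCATTCATGTTGCCAACAATTTTCTGCAGGGAAACGCCTTTATAATAAGACA
GTGGAAATAGTGGAGTATTGCACGACACATATTCCTTTAAAAAACAATCATCTGAATGATTTTAGCGTATTCAATTATCG
CCTTGAATCAAAACCTGGCGGTAATTCGCTAGATCCAGCTAAGCGTTCAGATCAAAATTGTGGGAATTTTCAAAAATACG
CTCAGTATTCCTATACTGATAAGCAAACTTCTCATCAGCTATGTAAGAGGGGTGGCTTTTTTGCTATACGTAATCTTTTA
CATGAGTGTTATCAGCCTAGAACTGGTAGAGCACAACAAAGTCATCTAGAATGTTGTGCATAA
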