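>kanMX_synthetic synthetic stand-in selection cassette (G418 resistance module placeholder)
CTAAAGTCATAAGATATACTGACCCAGTCTGAAATCTGCTGTGTCTACCCTGGGGTAATAATGGTGTTTTATCGATTTGC
CCAGTAAGTTTACAGTTTCATTTTGTCAGAGTAGGGTGACTTTAGTGAGACGGTCGCGGGGTATAGACACACAAAGTGCC
GCTGTTTGATTGTGTGATGCCAACGGTAGAAGCGATTCTTGCGTTCAAGTATCTCTGGTATGGGGAGAACCCATCTCATT
AACGGTTGGACAGGTTAGCTAAGAGAGTCTAGGTCCTTCTACATTATAGATTATGGGAATTGCTAATAGTACACCCCTTC
GCTATCGTCTTCGGGTGAATATGACTATGGTTGACTTTAACCCTCGTTGAAACAGTAAATAGCCTTATTCGTATTAAAGT
CGGCTAGACTACACGAATCGTGAGACAGACCATTTAATTATAATCAGTAACATAATTAAGCCATTATTCGAATTTATTTA
TTTAAACCTCCAAATAAAGAATAAAGTTTAACACCATATGACAACACGCCGAAGTGAGCGGTGTTGAATTCTCCGACACA
CTGGAAAGTTAGTCGTTACCATCTACTTAGTTTTACACATGATGTTTTTCATCCTTATCACTCACAAAGACAGTAGTCAC
AAACCGTAGTACTGACAAAAGGTTCCTGTAACAGCTTCCAAAACATAGATCGCATATAGAGATTAAGTTCTAAGATAGCT
TCAATGTCGTAATGGTCTCAAGCTGGTAGAACGCTCCCATACCAGCGATTTGAGCGAATAATTTAAACTTGGGTAGATCT
TTCGAACACGGAGACCTTATTTATGTTGTTGAATGATAATATGTTACGATCTTAAGTTCGGGTATCGTGTAGGAATCCAT
ATCTGTTCGGAGAAAATATCATCGATTGCCAAAGACGATGTTTTTTGTTAAAACTACATCTTTTTTAACGTAGGCATTTA
TACTTGTATAGACCACTTATCCCTTCTTCAACAACCCCTGTCACACCAAAATATATAGAATACGCAGTAAAATACGGAAT
GTGTTAAGATTCAAGATAACAAGCTCCATTTAAGAAAATATTATCGCTGCTGACATTTACTCCAAGTCTTAGTATTCGCG
TTTCCCACGGTTAAATAATTCAGACACGAGTCAATGGGTAGTTAGAAAGCCAGTCGAGGAAACTCTGATCTTCTGCTAAG
ACTTTCTATCTTGGTCGATTTCCATTTGGAGCATCCTACAGCGAGGTTACGAACCGACTATACATTTTCATAACAACAGA
CAAGATTCATATAATGAAAAGACTTAGAATTAAATATCCCGATGCCCGAGTCACTTTAAGTAAATCTTTAACACAATATT
AAACGGTGAACCGCACCTAA
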