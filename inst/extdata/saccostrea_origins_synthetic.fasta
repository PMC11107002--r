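>Sglo_origin_synth species=S. glomerata
TTCCATGAACTTCGCCCGCTCGTCTTATTTGTGGACACCGTGTTTGGAGCTTTCGCACCACTGAAATAAT
CAGGTCTGCGATGCACGATAAGGCGTCGCTGAGCACTTCGGGGTGTTCTAACCTTACCCCAGTAACCCCC
ATGTTCCTACCCAGGACCTACATTCCTCGCCGGGACCGTGGGTGTTGGGCTCGTCATAAGTGTGAATTTG
CGTAAGCAGGCCCAAGTTATTAAGGCACCCGCGGTGCGTTGAGAGGCAGGCCCTACTCCAACCTGAGAAA
CACCTAGCATATTAGCAATAGAAACTAGTCGGCTCAACCAGTCTTTATTAATACCACCGACTGGAACCCA
CGACTCAGGCGCTATGTTTAGGCGTCAGGTGTATCGGGTCTCCATACTGACAAGGGCGGCCAACATCGGG
TAACGGATTCGCGCTGGCCACCCCGGACTGACAGACTTTGCTTGTGTGAATCAGTATTCGCTAAGCGTGA
GGCGCCAGCCGCTGTATGGGGCGGACCCGTGGACCGTCGACTTAGTCGGTCGAGGAGGTTGAGTCTGCGA
TCGCCCGCACGAGAGTTTAGCAAAGTTCGGTGTATCACAC
>LinB_origin_synth species=lineage B
TTCCATGAACTTCGCCCGCTCCACTTATTTGTGGACTCCGTGTTTGGAGCTTTCGCAGCAGCCTAACGTA
CCGTATGCGGATGCACGCTAAGGCATCGCTTAGGATGCGAGTTTTATGTGACCCTACCTCAGTAACCCCC
ATGTTGCAACACAGGACCTAAAAGCCTCGCCGGGTCCGTGGGAGTTGTGCTCGTCATAAGTGTGAATTTT
CGTAAGCAGGCGCAAGACATTAAGGCCCCCGCGGTGCGTTGAGTGGCTGGCCGTATTCCATTGCTAACCG
GTTGTAGAACATTAGCAATAGAAACCAGTCGGCTCTACCAGTCTTTATTAATGCCACCGACTGGAACCCA
CGACTAAGGCGCTACGTTTAGGGGTCAGGTTTATCTCGTCTCCACCCTGACAAGGGCGGCCAACGTCGGG
TGCACCCTAACATCCCGGTACCCCGGAATGACAGACTTTGCTTGTGTTAATCAGTATTCGCTAAGCGGGA
GGTGCGAGCCGCTCTATGCGGCGGCACCGTGGACCGTCGACTTACTCGGTCGTGGAGGTTGTGTATGAGA
TCGACCGCACGGCAGTTTAGCAAAGTTCGGTGTATCACAC
>LinF_origin_synth species=lineage F
TTCCACGAACTTCGCCCCCTCCCCTTATTTGTGAACACCGTGTTTGGAGCTTTCGCAGCACTGCAATAAT
CAGGTCTGCGATGAACGCTAAGGCATCGCTTAGGATGCGAGTTTTAAGTGTGCTTGAGGACAGCGCGATA
ATGTTGCTACGCAGGACATAAAATCGTCGCCTGAACCGTGGGAGTTGTGCTCGTCATAAGTGTGAATTTG
CTTAAGCAGCCCCTAGATATTAAGGAACCCGCGGGGCGTTAAGAGGCTGGCCGTATTCCATTGCTAACCG
GTTGGCGAACAGTAGCAATAGAAACCAGTCTGCTCAACCAGTCTTTATTGATGCCACCGACTGGAACCCA
CGACTTAGGCGGGACGTTTAGGGGTCACGTGTATCGCGTCTCCATCCTGACAAGGGCGGCTGGGTGTTGA
ATGAACGTGCGCACTGGCCGCCCCGGAAAGACAGACTTTGCTTGTGTTAATCAGTATTCGCTAAGCGAGA
GGTGCGAGCCGCTCTATGGGGCGGCCCCGTGGACCGGCCACTTAGTCGGTCGTGGAGCTCGTGGATGAGC
TCGACCACACGGCAGTTTAGCAAAGTTCGGTGTACCACAC
>LinG_origin_synth species=lineage G
TTCCATGAACTTCGTCCGCTCCTCTTATTTGAGGACACCGTGTTTGGAGCTTTCGCAGTACTGCAATAAC
CAAGTCTGCGATGCACGCTAAGGCATCGCTTAGAATGCGAGTTTTATGTGACCGTACCCCAATAACCCAC
ATGTCGCTACCGGCCGATAGCAATATGTGACGGGACCGTGGGAGTTGTGCTCGTCAAAAGTGTGAATTTG
CGTAAGCAGGCCCAAGATATTAAGGCACACGCGGTGAGTTGAGAGGCTGGCCGTATTCCATTGCAAACCG
GTTGTAGAACATTAGCAATAGAAACGAGTCGGCCCAACCGGTCTTTATTCATGCCACCGACTGGAACCCA
CGACTAAGGCGCTCCGTTTAGGGGGATTTGTTCGTAGCGAACGCTCCTGACAACGGCGGCGAACATCGGG
TAACGGATCCGCACTGGCCACCCCGGAATGACAGACTTTGCGTTTGTTTATCAGTATTCGCTATGCGGGA
GGTGCGAGCCGCTCTATCGGGCGGCCCCGTGGACCGTCGACTTAGTCGGTCGTGGAGGTTGTGTTTGAGA
TCGACCGCACGGCACTTTAGCAAAGTTCGGTGTATTACAC
>Sspa_origin_synth species=S. spathulata
TTCCATGAACTTCGCCCGCTCCTCTTTTTTGTGGACACCGAGTTTGGAGCTTTCGCAGCACTGCCATAAT
CACGTCTGCGATGCACGCTAAGGCATCGCCTAGGATGCGAGTTTTATGTGACCGTACCCTTATAACCCCC
ATGTGGTTACCCAGGACCTAAAAACCTCGCCGGGACCGTGGGAGCTGTGCTCGTCATAAGGCGGTAGCTC
TGTTGCGATGCCCAAGATATGAAGGCACCCGCGGTGCGTTGAGAGGCTGGCCGTATTCCATTGCTAACCG
TCATCCGCGAGTTAAATCGTGAAACCAGTTGGCTCAACCAGACTTTATTAATGCCACCGACTGGAACCCA
CGACTAAGGCGCTACGTTTCGGAGTCAGCTGTATCGCGTCTCCATCCTGACAAGGGCGGCCAACATCGGG
TAACGGATTCGCACAGGCCACCCCGGAATGCCGGACTTTGATTGTGTTGATCAGTATTCGCTAAGAGGGA
GGTGCGAGTCGCTCTATGTGGCGGCCCAGTGGACCGTCGACTTAGTCGGTCGTGAAAGTGGTGTACGAGA
TCGACCGTACGGCAGTTTATCAAAGTTCGGTGTATCACAC
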