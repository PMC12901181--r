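>attI1_synthetic synthetic stand-in for the canonical 65 bp attI1 site
TGCACCTGCATCAGCTGACCTGCAGTCTGACCCCTAAATCGTTTCAGGAAACAAAGTTAG
ACGGT
>attI2_synthetic synthetic stand-in for the 311 bp attI2 region
TTCTAAACTAACGGTGTCGCGCGAGCCATGCGACCGCTTGCCAGGTGCTTCTGTGATATG
TAAACTAGCTCAAATGGTGGTGTGATATGAAGTCAAGCTTGAGTCTTAGAGCAAGGAAGT
GTCTTAACAGTGCTCTGAGACGCGTGTGTGATTACATCATACTAGCGCGGGTTGTAAATG
TTGACCGGCCCTCAGAGGAGTAGGGCTCCCAGGACAGCTCAGCGGCAATGGGGACGCTCC
TGGAACTCACAGCTCGTCGAATAACAGTAGCAATACTTTCATCGAGTTGTGCAGTGAATA
AAATGTTAAAC
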