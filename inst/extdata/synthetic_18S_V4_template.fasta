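>synthetic_18S_V4_template synthetic stand-in; one 421 bp TAReuk454FWD1/TAReukREV3 product
GTCCCGCGGCCCGCGATTGCGCCCTACAGCATGGGTAACTAGTGTTGCCAATAGACCGCGCCAGCACCCG
CGGTAATTCCTATCCGTAATCCGTATGTGATGTCAATTCACGAATGCTTCCGCATGAAATGAGGGTTCGT
CCCCGTTGAAAAACTTGTAAAATTCCCTTATTCCCGGCGGAGATGTGGGAGAAGAAACCATGGTCAAGAT
CGTTCTGTGGGCTATGACTGTCAATATTTATACGGTACCTGGGGGTACGGCACGCTGGAGGGAATAGTAG
TTCTGACGACAAGGCACCCCACCGGATCGCCGATCCTGTAAAACAAAGAGCTTCTATCACCCTCAAGGCG
GGGGTGTAGGCCAGAAACATACTGGCTTATATTTTATTTTGCCGTCCGCCCCCTCTCACCGGTCCCCCTT
TTGGGATCTGAGAGTCTGAATACAACCCGAAGCGCGTTTTCGGTTGATCAAGAACGAAAGTCGCGGGGCG
GTATAATTGTAGGATCCTCAGGCGGGGTTGGTCTTAGCTGTACGCATGTGC
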