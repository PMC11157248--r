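>synthetic_alphoid_consensus 171bp synthetic AT-rich stand-in (not a published alphoid consensus)
CCCTGCTTCCTCAACGGATAATTGTGTAAACTCTAATGTATATGTATCTAACAAGCGGTAATCGATGTTTCGGTAATAAA
ATCGTTTTTAGCGCCAGGACGCCAAATATTACCGATATTAGTTTTCTTGGGTTTTGTAACATAACGGTCTATATCTCATA
AGCAGGTCGTA
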