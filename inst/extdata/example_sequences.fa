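>mps 139-nt minimal promoter sequence (basal context for binding-site comparisons)
TCACTATATATAGGAAGTTCATTTCATTTGGAATGGACACGTGTTGTCATTTCTCAACAA
TTACCAACAACAACAAACAACAAACAACATTATACAATTACTATTTACAATTACATCTAG
ATAAACAATGGCTTCCTCC
>spacer24_example AAAG(N)ACGT worked example with a 24-nt spacer
AAAGTTGGGCTTTCAAAATTGTTAACTCACGT
>spacer14_example ACGT(N)AAAG worked example with a 14-nt spacer
ACGTGGATGCTATTATTAAAAG
>cloning_insert BamHI-flanked 50-nt random cloning insert
GGATCCGGCTATGGCGGAGCAAGATTCACTCTGCGAGGCCAAAGCTTACCCCGGAAGGAT
CC
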