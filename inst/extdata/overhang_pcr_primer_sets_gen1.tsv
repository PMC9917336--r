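set	fwd	rev
1	ACACTCTTTCCCTACACGACGCTCTTCCGATCTCCAGTCCTCAACAAGCTG	GTTGAAGCCGGTTACCAC
2	ACACTCTTTCCCTACACGACGCTCTTCCGATCT	TTCTGGGTTCCTCATCGCNNNNNNNNGTTGAAGCCGGTTACCAC
3	ACACTCTTTCCCTACACGACGCTCTTCCGATCT	GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCTTTCTGGGTTCCTCATCGC
4	AATGATACGGCGACCACCGAGATCTACACTCTTTCCCTACACGACGCTCTTCCGATCT	CAAGCAGAAGACGGCATACGAGATNNNNNNNNNNATATTCACGTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT
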