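generation	role	sequence	design_source
gen1	fwd	CCAGTCCTCAACAAGCTG	Primer3
gen1	rev	GTTGAAGCCGGTTACCAC	Primer3
gen1	traptag	TTCTGGGTTCCTCATCGC	Primer3
gen2	fwd	AGTGCGTGCAGTGAAAGC	Primer3
gen2	rev	ATGGCGTTGCAAAGTCGG	Primer3
gen2	traptag	CGCCTTGATTTCAACTCGGCTCTCCGCTGAACA	NUPACK
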