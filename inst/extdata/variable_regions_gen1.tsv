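block	variant	sequence
1	1	TGCGGC
1	2	GCGGGC
1	3	TGGGCG
1	4	CGCCGG
2	1	GGCGTC
2	2	CCCGGC
2	3	CCTACC
2	4	GCACAG
3	1	AGCGGG
3	2	GCGGAA
3	3	GCTGCC
3	4	GCGGGC
4	1	CGCTCC
4	2	ACTCGT
4	3	ACGCGG
4	4	CCTTTG
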