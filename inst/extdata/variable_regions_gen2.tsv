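block	variant	sequence
1	1	ATCGACTGCGAG
1	2	GCTAGCACTGAG
1	3	GTGTGCGCTAGC
1	4	TGCTCTAGTAGC
1	5	CGATACGAGATC
1	6	ACTGAGTGTCTC
1	7	TGCAGTGACTAG
1	8	AGCGTGACGCGT
2	1	ATGACGAGTGCT
2	2	GAGATCTGCAGT
2	3	CTATCGCGACGT
2	4	CATGCTGTCAGC
2	5	CGACGTCTATCG
2	6	GAGTCTACGTCG
2	7	GTCGCAGTACAG
2	8	ACAGTGATCGAC
3	1	TGTCTCGAGTCT
3	2	GCGCTGCTACTG
3	3	CACTCAGATGTG
3	4	GATGTGCAGAGA
3	5	TCTCGTCGTATG
3	6	CAGCAGTCTCGT
3	7	CAGAGACAGCAG
3	8	ATAGCGCACTCA
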