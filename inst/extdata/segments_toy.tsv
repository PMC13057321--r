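class	name	family	cdr1_aa	cdr2_aa	sequence	anchor_offset
V	TRBV4-1	TRBV4	MGHRA	VFLMV	TGTGCCAGCAGT
V	TRBV7-2	TRBV7	SGHTA	FVLMW	TGTGCCAGCAGC
V	TRBV29-1	TRBV29	MNHNS	YFSET	TGTAGCGTTGAA
D	TRBD1				GGGACAGGGGGC
D	TRBD2				GGGACTAGCGGGGGG
J	TRBJ1-1				AATACTGAAGCTTTCTTTGGCCAAGGC	15
J	TRBJ1-2				AACTATGGCTACACCTTCGGTTCG	15
J	TRBJ2-1				AATGAGCAGTTCTTCGGGCCA	12
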