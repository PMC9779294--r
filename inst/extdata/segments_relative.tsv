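# Published TSS-relative coordinates (kb, transcription-direction positive)
# of the reported genomic segments: S = histone-PTM enriched segments
# (7 brain regions), A = DNase accessibility segments (fetal tissues),
# B = ATAC accessibility segments (adult brain, hg38 anchor),
# H = consistently hypomethylated segments (mid-frontal gyrus, 6 ages).
set	label	start_kb	end_kb	assembly
S	S1	-1	7	hg19
S	S2	13	15	hg19
S	S3	20	25	hg19
S	S4	32	42	hg19
S	S5	46	59	hg19
S	S6	61	72	hg19
S	S7	73	79	hg19
S	S8	83	87	hg19
S	S9	94.5	96.3	hg19
S	S10	112	117	hg19
S	S11	122	135	hg19
A	A1	-0.5	0.1	hg19
A	A2	0.4	0.8	hg19
A	A3	46.3	46.4	hg19
A	A4	50.9	51.3	hg19
A	A5	77.7	77.9	hg19
A	A6	83.8	84.0	hg19
A	A7	124.4	127.4	hg19
A	A8	144.1	144.4	hg19
A	A9	150.1	150.4	hg19
B	B1	-0.8	1.7	hg38
B	B2	50.8	51.6	hg38
B	B3	77.2	77.9	hg38
B	B4	83.8	85.6	hg38
B	B5	95.0	95.5	hg38
B	B6	124.7	127.7	hg38
B	B7	130.4	131.4	hg38
B	B8	144.1	144.3	hg38
B	B9	6.5	7.0	hg38
H	H1	-1.1	3.7	hg19
H	H2	4.6	5.4	hg19
H	H3	50.2	51.5	hg19
H	H4	77.1	78.7	hg19
H	H5	83.9	84.1	hg19
H	H6	124.2	129.4	hg19
H	H7	144.0	144.4	hg19
H	H8	147.5	150.0	hg19
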