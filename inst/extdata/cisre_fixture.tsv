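# SYNTHETIC cis-regulatory element fixture (TSS-relative kb, hg19 anchor).
# The published record does not print genomic coordinates for the F-series
# elements; these intervals are user-replaceable placeholders positioned to
# be consistent with the qualitative containment statements (e.g. the F3
# silencer aligning with the H2 hypomethylated segment, F11/F13 inside S7,
# F16 inside S9 and B5, F21 inside S11/H6, the promoter elements and the
# silencer of astrocytoma around the TSS). Replace with measured
# coordinates for real analyses.
label	role	start_kb	end_kb	assembly
core promoter	promoter	-0.2	0	hg19
proximal promoter	promoter	-0.6	-0.2	hg19
distal promoter	promoter	-1.0	-0.6	hg19
silencer of astrocytoma	silencer	-0.4	-0.1	hg19
weak silencer	silencer	-0.9	-0.5	hg19
universal enhancer	enhancer	-1.1	-0.9	hg19
F3	silencer	4.6	5.4	hg19
F11	enhancer	75.0	75.5	hg19
F13	silencer	76.0	76.4	hg19
F16	enhancer	95.0	95.5	hg19
F17	enhancer	113.0	113.5	hg19
F21	enhancer	125.0	126.0	hg19
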