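# Expected completeness of exons and functional domains in the four
# NCBI-style protein isoforms, transcribed cell-for-cell into the package's
# categorical vocabulary (free-text remarks such as the alternative-Met
# annotations are dropped; capitalisation normalised).
feature	isoform1	isoform2	isoform3	isoform4
exon1	-	✓	-	-
exon2	✓	-	-	-
exon3	✓	✓	N-term. incompl.	-
exon4	✓	✓	✓	N-term. incompl.
HMGD1	✓	Possible different N-terminus	-	-
HMGD2	✓	✓	✓	-
MBD	✓	✓	N-term. incompl.	-
aDBD	✓	✓	✓	N-term. incompl.
TRD	✓	✓	✓	N-term. incompl.
NLS1	✓	✓	✓	-
NLS2	✓	✓	✓	✓
AT-hook 1	✓	✓	✓	-
AT-hook 2	✓	✓	✓	✓
H3-M-T IS	✓	✓	N-term. incompl.	-
NID	✓	✓	✓	✓
TBL1XR1 IS	✓	✓	✓	✓
WW-2 IS	✓	✓	✓	✓
CTDalpha	✓	✓	✓	✓
CTDbeta	✓	✓	✓	✓
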