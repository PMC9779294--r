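# Expected completeness of exons and functional domains in the eight
# predicted database-style isoforms, transcribed cell-for-cell into the
# package's categorical vocabulary (capitalisation normalised). The NLS,
# AT-hook and CTDbeta sequences are absent from every predicted isoform.
feature	B5MCB4	A0A0D9SFX7	C9JH89	A0A1B0GTV0	A0A0D9SEX1	H7BY72	A0A6Q8PHQ3	A0A6Q8PF93
exon1	✓	-	-	-	-	-	-	-
exon2	-	✓	✓	-	✓	C-term. incompl.	✓	✓
exon3	✓	✓	C-term. incompl.	-	C-term. incompl.	-	-	-
exon4	C-term. incompl.	C-term. incompl.	-	C-term. incompl, missing fragment inside	-	-	-	-
HMGD1	Possible different N-terminus	✓	C-term. incompl.	-	C-term. incompl.	C-term. incompl.	C-term. incompl.	C-term. incompl.
HMGD2	-	C-term. incompl.	-	-	-	-	-	-
MBD	C-term. incompl.	C-term. incompl.	-	N-term. and C-term. incompl.	-	-	-	-
aDBD	-	-	-	N-term. incompl.	-	-	-	-
TRD	-	-	-	N-term. incompl.	-	-	-	-
NLS1	-	-	-	-	-	-	-	-
NLS2	-	-	-	-	-	-	-	-
AT-hook 1	-	-	-	-	-	-	-	-
AT-hook 2	-	-	-	-	-	-	-	-
H3-M-T IS	✓	✓	-	-	-	-	-	-
NID	-	-	-	N-term. incompl.	-	-	-	-
TBL1XR1 IS	-	-	-	N-term. incompl.	-	-	-	-
WW-2 IS	-	-	-	-	-	-	-	-
CTDalpha	-	-	-	C-term. incompl.	-	-	-	-
CTDbeta	-	-	-	-	-	-	-	-
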