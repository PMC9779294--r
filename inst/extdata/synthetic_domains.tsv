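# SYNTHETIC functional-domain fixture: coordinates are generated
# placements on the E2-style reference product (isoform1),
# internally consistent with the synthetic isoform architecture.
# Swap in measured coordinates (with their citation tags) for real
# analyses.
name	ref_isoform	start	end	source
HMGD1	isoform1	1	55	synthetic placement
MBD	isoform1	78	165	synthetic placement
H3-M-T IS	isoform1	85	115	synthetic placement
HMGD2	isoform1	157	190	synthetic placement
aDBD	isoform1	168	252	synthetic placement
NLS1	isoform1	173	193	synthetic placement
AT-hook 1	isoform1	184	195	synthetic placement
TRD	isoform1	207	310	synthetic placement
NID	isoform1	225	262	synthetic placement
TBL1XR1 IS	isoform1	228	258	synthetic placement
NLS2	isoform1	330	346	synthetic placement
AT-hook 2	isoform1	350	361	synthetic placement
WW-2 IS	isoform1	365	375	synthetic placement
CTDalpha	isoform1	300	420	synthetic placement
CTDbeta	isoform1	425	486	synthetic placement
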