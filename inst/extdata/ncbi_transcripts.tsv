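# Mirror of the NCBI reference-transcript summary for the human MECP2 gene
# (Gene ID 4204), reviewed NM_ records and their annotated protein products,
# as of 15 October 2022. Transcribed by hand for download-free examples.
accession	source_db	product_isoform	review_status	evidence	biotype	tsl	cds_incomplete
NM_004992.4	NCBI	isoform 1	reviewed	supporting mRNA and EST evidence	protein coding	-	-
NM_001110792.2	NCBI	isoform 2	reviewed	supporting mRNA and EST evidence	protein coding	-	-
NM_001316337.2	NCBI	isoform 3	reviewed	supporting mRNA and EST evidence	protein coding	-	-
NM_001369391.2	NCBI	isoform 3	reviewed	supporting mRNA and EST evidence	protein coding	-	-
NM_001369392.2	NCBI	isoform 3	reviewed	supporting mRNA and EST evidence	protein coding	-	-
NM_001369393.2	NCBI	isoform 3	reviewed	supporting mRNA and EST evidence	protein coding	-	-
NM_001369394.2	NCBI	isoform 3	reviewed	supporting mRNA and EST evidence	protein coding	-	-
NM_001386137.1	NCBI	isoform 4	reviewed	supporting mRNA and EST evidence	protein coding	-	-
NM_001386138.1	NCBI	isoform 4	reviewed	supporting mRNA and EST evidence	protein coding	-	-
NM_001386139.1	NCBI	isoform 4	reviewed	supporting mRNA and EST evidence	protein coding	-	-
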