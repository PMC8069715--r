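##fileformat=VCFv4.2
##contig=<ID=chr1>
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
chr1	21341446	rs331051321	C	T	.	.	.
chr1	21349510	rs331477147	G	C	.	.	.
chr1	21350000	.	A	AT	.	.	.
chr1	21368747	rs327656939	A	G	.	.	.
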