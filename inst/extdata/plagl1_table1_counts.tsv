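chrom	pos	ref	alt	rs_id	sample	source	tissue	ref_count	alt_count	other_count
chr1	21341446	C	T	rs331051321	P1	gDNA	.	10	12	0
chr1	21341446	C	T	rs331051321	P1	RNA	Ad	0	26	0
chr1	21341446	C	T	rs331051321	P1	RNA	Ln	2	35	0
chr1	21341446	C	T	rs331051321	P1	RNA	Hr	0	25	0
chr1	21341446	C	T	rs331051321	P1	RNA	Ov	0	33	0
chr1	21341446	C	T	rs331051321	P2	gDNA	.	6	10	0
chr1	21341446	C	T	rs331051321	P2	RNA	Ad	0	24	0
chr1	21341446	C	T	rs331051321	P2	RNA	Ln	0	26	0
chr1	21341446	C	T	rs331051321	P2	RNA	Hr	0	33	0
chr1	21341446	C	T	rs331051321	P2	RNA	Ov	0	24	0
chr1	21349510	G	C	rs331477147	P1	gDNA	.	7	8	0
chr1	21349510	G	C	rs331477147	P1	RNA	Ad	0	19	0
chr1	21349510	G	C	rs331477147	P1	RNA	Ln	0	11	0
chr1	21349510	G	C	rs331477147	P1	RNA	Hr	0	35	0
chr1	21349510	G	C	rs331477147	P1	RNA	Ov	0	22	0
chr1	21349510	G	C	rs331477147	P2	gDNA	.	10	14	0
chr1	21349510	G	C	rs331477147	P2	RNA	Ad	0	11	0
chr1	21349510	G	C	rs331477147	P2	RNA	Ln	0	11	0
chr1	21349510	G	C	rs331477147	P2	RNA	Hr	0	30	0
chr1	21349510	G	C	rs331477147	P2	RNA	Ov	0	20	0
chr1	21349510	G	C	rs331477147	P3	gDNA	.	12	25	0
chr1	21349510	G	C	rs331477147	P3	RNA	Ad	22	0	0
chr1	21349510	G	C	rs331477147	P3	RNA	Ln	33	0	0
chr1	21349510	G	C	rs331477147	P3	RNA	Hr	37	0	0
chr1	21349510	G	C	rs331477147	P3	RNA	Ov	19	0	0
chr1	21365021	T	A	.	P2	gDNA	.	9	6	0
chr1	21365021	T	A	.	P2	RNA	Ad	51	1	0
chr1	21365021	T	A	.	P2	RNA	Ln	46	0	0
chr1	21365021	T	A	.	P2	RNA	Hr	60	0	0
chr1	21365021	T	A	.	P2	RNA	Ov	40	0	0
chr1	21368747	A	G	rs327656939	P3	gDNA	.	8	13	0
chr1	21368747	A	G	rs327656939	P3	RNA	Ad	37	1	0
chr1	21368747	A	G	rs327656939	P3	RNA	Ln	48	1	0
chr1	21368747	A	G	rs327656939	P3	RNA	Hr	52	0	0
chr1	21368747	A	G	rs327656939	P3	RNA	Ov	63	2	0
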