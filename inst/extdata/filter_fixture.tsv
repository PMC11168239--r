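chrom	pos	ref	alt	gene	func_region	exonic_func	consequence	variant_type	max_af
1	101	A	G	G01	exonic	nonsynonymous SNV	missense_variant	snv	.
1	102	C	T	G02	exonic	nonsynonymous SNV	missense_variant	snv	0.005
1	103	G	A	G03	exonic	nonsynonymous SNV	missense_variant	snv	0.30
1	104	T	C	G04	exonic	synonymous SNV	synonymous_variant	snv	0.002
1	105	A	T	G05	exonic	stopgain	stop_gained	snv	.
1	106	G	C	G06	splicing	.	splice_donor_variant	snv	0.001
1	107	C	G	G07	intronic	.	intron_variant	snv	.
1	108	ATTG	A	G08	exonic	frameshift deletion	frameshift_variant	deletion	.
1	109	GCCA	G	G09	exonic	nonframeshift deletion	inframe_deletion	deletion	0.004
1	110	A	C	G10	exonic	.	start_lost	snv	.
1	111	T	G	G11	UTR3	.	3_prime_UTR_variant	snv	.
1	112	C	CAGG	G12	exonic	nonframeshift insertion	inframe_insertion	insertion	.
1	113	G	GA	G13	exonic	frameshift insertion	frameshift_variant	insertion	0.05
1	114	A	G	G14	exonic	synonymous SNV	synonymous_variant	snv	.
1	115	T	A	G15	upstream	.	upstream_gene_variant	snv	0.0001
1	116	G	T	G16	exonic	unknown	coding_sequence_variant	snv	.
1	117	C	A	G17	exonic	stoploss	stop_lost	snv	0.001
1	118	A	T	G18	intergenic	.	intergenic_variant	snv	.
1	119	G	A	G19	intronic	.	splice_region_variant	snv	0.002
1	120	T	C	G20	exonic	nonsynonymous SNV	missense_variant,splice_region_variant	snv	0.009
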