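# Example two-cohort replication screen: per-SNP association summaries for
# eight COPD candidate SNPs that reached p < 0.1 in the first (larger)
# screen cohort. Columns: first-screen effect direction on disease risk and
# p-value; second-screen odds ratio and p-value; discovery-analysis odds
# ratio and p-value (OR missing where the discovery evidence came from the
# meta-analysis, whose p is shown).
snp_id	chrom	pos	gene	screen1_direction	screen1_p	screen2_or	screen2_p	discovery_or	discovery_p
rs1999261	6	6515106	INTERGENIC	Increase	0.042	0.94	0.53	1.15	0.0080
rs1265098	6	31214156	PSORS1C1	Increase	0.024	1.20	0.098	1.18	0.0065
rs4750277	10	12954527	INTERGENIC	Increase	0.0062	0.97	0.80	0.83	0.0097
rs1025607	12	94884637	AMDHD1	Increase	0.011	1.12	0.26	NA	0.0089
rs2347279	18	2528545	METTL4	Decrease	0.097	1.01	0.91	0.83	0.0025
rs1878553	18	2560155	NDC80	Decrease	0.030	1.03	0.83	0.83	0.0028
rs4803481	19	46758396	INTERGENIC	Decrease	0.055	0.97	0.81	NA	0.0043
rs2302188	19	46777713	CEACAM21	Decrease	0.090	0.97	0.77	0.85	0.0075
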