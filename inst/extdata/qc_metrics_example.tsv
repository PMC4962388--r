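sample_id	total_reads	pct_exonic	genes_detected	ercc_ratio
cell01	1200000	62.1	8421	0.12
cell02	310000	45.0	7003	0.48
cell03	250000	45.0	7000	0.50
cell04	900000	39.0	5000	0.70
cell05	510000	71.5	9102	0.05
cell06	140000	55.2	6500	0.22
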