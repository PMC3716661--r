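chrom	n_markers	total_cM
SBI-01	139	166.6
SBI-02	102	152.2
SBI-03	127	147.7
SBI-04	92	131.4
SBI-05	43	105.3
SBI-06	64	113.6
SBI-07	76	105.4
SBI-08	55	96.0
SBI-09	58	112.3
SBI-10	85	102.2
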