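transcript_id	gene	chrom	strand	exons	cds_start	cds_end
MAD2L1BP_synthetic	MAD2L1BP	chr6	+	43599800-43599919,43600931-43601090,43602000-43602298,43607829-43608470	43599900	43608270
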