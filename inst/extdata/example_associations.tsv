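snp_id	statistic	p_value	n_effective	note
rs0001_01	1.38	0.197	30	
rs0002_01	3.56	0.237	30	
rs0002_02	1.04	0.039	30	
rs0002_03	2.27	0.064	30	
rs0002_04	4.67	0.219	30	
rs0003_01	1.04	0.236	30	
rs0003_02	5.99	0.296	30	
rs0003_03	2.3	0.0883	30	
rs0003_04	4.03	0.029	30	
rs0003_05	4.57	0.229	30	
rs0003_06	0.9	0.361	30	
rs0004_01	0.61	0.0157	30	
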