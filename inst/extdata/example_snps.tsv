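snp_id	chrom	pos
rs0001_01	chr1	15251
rs0002_01	chr2	15251
rs0002_02	chr2	15751
rs0002_03	chr2	16251
rs0002_04	chr2	16751
rs0003_01	chr3	15251
rs0003_02	chr3	15751
rs0003_03	chr3	16251
rs0003_04	chr3	16751
rs0003_05	chr3	17251
rs0003_06	chr3	17751
rs0004_01	chr4	15251
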