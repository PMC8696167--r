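gene_id	chrom	start	end	strand
G0001	chr1	15001	15501	+
G0002	chr2	15001	17001	-
G0003	chr3	15001	18001	+
G0004	chr4	15001	18001	-
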