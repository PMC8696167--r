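PATHWAY_A	synthetic example	G0001	G0002	G0003
PATHWAY_B	synthetic example	G0002	G0003	G0004
PATHWAY_C	synthetic example	G0001	G0002	G0003	G0004
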