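gene_id	antennae	legs	head	wings	pheromone_gland
BmorCSP1	14	6	9	5	27
BmorCSP2	6	5	5	8	19
BmorCSP4	12	14	1	2	9
BmorCSP14	20	13	16	17	25
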