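TOY001	glycan processing (synthetic)	gene_001	gene_002	gene_003	gene_004	gene_005	gene_006
TOY002	growth factor signaling (synthetic)	gene_005	gene_006	gene_007	gene_008	gene_009	gene_010	gene_011
TOY003	cell adhesion (synthetic)	gene_012	gene_013	gene_014	gene_015
TOY004	lipid metabolism (synthetic)	gene_016	gene_017	gene_018	gene_019	gene_020	gene_021
TOY005	chromatin regulation (synthetic)	gene_001	gene_010	gene_020	gene_030	gene_040
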