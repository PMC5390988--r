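table	label	n_snps	dbar	ka	ks	ratio
selection_screen	salivary_kazal_proteinase_inhibitor	NA	NA	0.00539	1.08e-4	50
selection_screen	salivary_lipocalin	NA	NA	0.07865	6.9827e-2	1.12635
selection_screen	odorant_binding_protein_rproobp4	NA	NA	0.002812	5.62e-5	50
selection_screen	hemolysin_like_secreted_salivary_protein_2	NA	NA	0.011252	2.25e-4	50
selection_screen	heme_binding_protein	NA	NA	0.028048	5.61e-4	50
selection_screen	diptericin	NA	NA	0.046749	9.35e-4	50
selection_screen	nitrophorin_3b	NA	NA	0.117836	1.12417	0.719394
fixed_markers	c10228_g1_i1	4	1	3.94e-3	7.90e-5	50
fixed_markers	c10808_g1_i1	6	1	1.86e-2	3.7e-4	50
fixed_markers	c11678_g1_fi1	4	1	6.33e-3	1.3e-4	50
fixed_markers	c13526_g1_i2	4	1	8.62e-3	5.28e-3	1.63269
fixed_markers	c13603_g1_i1	6	0.9993	1.59e-2	1.09e-2	1.45733
fixed_markers	c41453_g1_i1	2	0.9969	8.44e-3	1.7e-4	50
fixed_markers	c13063_g1_i1	7	0.9959	3.63e-3	7.30e-5	50
fixed_markers	c10204_g1_i1	10	0.9949	6.67e-3	1.3e-4	50
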