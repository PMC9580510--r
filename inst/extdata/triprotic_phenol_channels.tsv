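mechanism	site	solvent	species_label	dG_reaction	dG_activation	imaginary_frequency	symmetry_number	present
FHT	1	water	H3W	-0.82	NA	NA	1	TRUE
FHT	2	water	H3W	-6.14	NA	NA	1	TRUE
FHT	3	water	H3W	-1.47	NA	NA	1	TRUE
SET	SET	water	H3W	33.61	NA	NA	1	TRUE
FHT	1	water	H2W-	-13.46	NA	NA	1	TRUE
FHT	2	water	H2W-	NA	NA	NA	1	FALSE
FHT	3	water	H2W-	-12.56	NA	NA	1	TRUE
SET	SET	water	H2W-	5.25	NA	NA	1	TRUE
FHT	1	pentyl ethanoate	H3W	0.63	NA	NA	1	TRUE
FHT	2	pentyl ethanoate	H3W	-5.43	NA	NA	1	TRUE
FHT	3	pentyl ethanoate	H3W	-0.06	NA	NA	1	TRUE
SET	SET	pentyl ethanoate	H3W	NA	NA	NA	1	FALSE
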