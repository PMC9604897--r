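olya6_gene	reactant	re1
re1	product	olya6_mrna
olya6_mrna	reactant	re2
re2	product	pleurotolysin
pleurotolysin	reactant	re3
membrane_receptor	reactant	re3
re3	product	cell_differentiation
cell_differentiation	reactant	re4
re4	product	mycelium_aggregation
fbh1_gene	reactant	re5
re5	product	fbh1_mrna
humidity	modifier	re5
mycelium_aggregation	reactant	re6
re6	product	pinhead_formation
hydrophobin	modifier	re6
pofst_protein	modifier	re6
fbh1_mrna	reactant	re7
re7	product	hydrophobin
pofst_gene	reactant	re8
re8	product	pofst_mrna
pofst_mrna	reactant	re9
re9	product	pofst_protein
powc1_gene	reactant	re10
re10	product	powc1_mrna
blue_light	modifier	re10
powc1_mrna	reactant	re11
re11	product	powc1_protein
gapdh_gene	reactant	re12
re12	product	gapdh_mrna
powc1_fad_complex	modifier	re12
re13	product	structural_proteins
laccase	modifier	re13
atp	modifier	re13
gapdh_mrna	reactant	re14
re14	product	gapdh_protein
pgd6_gene	reactant	re15
re15	product	pgd6_mrna
powc1_fad_complex	modifier	re15
pinhead_formation	reactant	re16
re16	product	fruit_body_development
structural_proteins	modifier	re16
atp	modifier	re16
pepck_gene	reactant	re17
re17	product	pepck_mrna
powc1_fad_complex	modifier	re17
pepck_mrna	reactant	re18
re18	product	pepck_protein
re19	product	pep
g6pd_protein	modifier	re19
pfk_protein	modifier	re19
pep	reactant	re20
dahp_synthase	reactant	re20
re20	product	shikimic_acid
pep	reactant	re21
re21	product	atp
re21	product	reactive_oxygen
gapdh_protein	modifier	re21
re22	product	phenolic_compounds
pal1_protein	modifier	re22
pal1_gene	reactant	re23
re23	product	pal1_mrna
pal1_mrna	reactant	re24
re24	product	pal1_protein
polac_gene	reactant	re25
re25	product	polac_mrna
pal2_gene	reactant	re26
re26	product	pal2_mrna
pal2_mrna	reactant	re27
re27	product	pal2_protein
re28	product	pigments
pal2_protein	modifier	re28
re29	product	membrane_receptor
polac_mrna	reactant	re30
re30	product	polac12_rna_complex
lignin	reactant	re31
re31	product	phenolic_compounds
re31	product	pigments
polac12_rna_complex	modifier	re31
fruit_body_development	reactant	re32
dahp_synthase	reactant	re33
g6pd_protein	reactant	re34
pfk_protein	reactant	re35
re36	product	mycelium_aggregation
fruit_body_development	modifier	re36
powc1_protein	reactant	re37
fad	reactant	re37
re37	product	powc1_fad_complex
membrane_receptor	reactant	re38
re39	product	atp
pepck_protein	modifier	re39
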