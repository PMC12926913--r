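group_id	family_id	kind	expected_domains	expected_motifs	anchor_ref	clamp_region	divergence	notes
PolA1	A	polymerase	FEN-exo,DnaQ-exo,Pol-core-A	FEN_AS:required,DEDDy:typical,CAT_A:required	grp_PolA1		0.225	Pol I orthologs; canonical three-domain architecture
PolA1-like	A	polymerase	DnaQ-exo,Pol-core-A	DEDDy:typical,CAT_A:required	grp_PolA1-like		0.225	Pol I-like, lacking the 5'-3' exonuclease domain
PolA2	A	polymerase	DnaQ-exo,Pol-core-A	DEDDy:absent,CAT_A:required,CLAMP:required	grp_PolA2	exo_loop	0.225	Actinobacterial; vestigial proofreader with beta-clamp motif
PolA3	A	polymerase	DnaQ-exo,Pol-core-A	DEDDy:required,CAT_A:required	grp_PolA3		0.225	phage-related accessory group
G1	B	polymerase	PolB-NT,DnaQ-exo,Pol-core-B	DEDDy:required,CAT_B:required	grp_G1		0.225	Pol II orthologs
G2	B	polymerase	PolB-NT,DnaQ-exo,Pol-core-B	DEDDy:absent,CAT_B:required	grp_G2		0.225	PolB2-derived TLS group, dead proofreader
G3	B	polymerase	PolB-NT,DnaQ-exo,Pol-core-B	DEDDy:required,CAT_B:required	grp_G3		0.225	Pol epsilon N-half-like group
G4	B	polymerase	DnaQ-exo,Pol-core-B	DEDDy:typical,CAT_B:required	grp_G4		0.225	
G5	B	polymerase	DnaQ-exo,Pol-core-B	DEDDy:typical,CAT_B:required	grp_G5		0.225	
G6	B	polymerase	DnaQ-exo,Pol-core-B	DEDDy:typical,CAT_B:required	grp_G6		0.225	
G7	B	polymerase	DnaQ-exo,Pol-core-B	DEDDy:typical,CAT_B:required	grp_G7		0.225	
G8	B	polymerase	DnaQ-exo,Pol-core-B	DEDDy:typical,CAT_B:required	grp_G8		0.225	
PolC	C	polymerase	PHP,DnaQ-exo,Pol-core-C	PHP_AS:required,DEDDh:required,CAT_C:required	grp_PolC		0.225	replicative alpha subunit with embedded DnaQ domain
DnaE1	C	polymerase	PHP,Pol-core-C,OB,CTD	PHP_AS:required,CAT_C:required	grp_DnaE1		0.225	replicative alpha subunit, E. coli Pol III type
DnaE3	C	polymerase	PHP,Pol-core-C,OB,CTD	PHP_AS:absent,CAT_C:required	grp_DnaE3		0.225	replicative alpha subunit co-occurring with PolC
DnaE2A	C	polymerase	PHP,Pol-core-C	PHP_AS:absent,CAT_C:required	grp_DnaE2A		0.225	error-prone; partners with ImuA and ImuB
DnaE2B	C	polymerase	PHP,Pol-core-C	PHP_AS:absent,CAT_C:required	grp_DnaE2B		0.225	error-prone; PolY/ImuB-C partnered
DnaE2X	C	polymerase	PHP,Pol-core-C	PHP_AS:absent,CAT_C:required	grp_DnaE2X		0.225	error-prone; split-ImuB partnered
PolX1	X	polymerase	8kDa,Pol-core-X,PHP	PHP_AS:required,CAT_X:required	grp_PolX1		0.225	canonical bacterial PolX
PolX2	X	polymerase	Pol-core-X,CTD	CAT_X:required	grp_PolX2		0.225	PHP-less group with novel C-terminal domain
PolX-like	X	polymerase	PHP	PHP_AS:required	grp_PolX-like		0.225	PolX1 homologs lacking the entire polymerase domain
UmuC	Y	polymerase	Pol-core-Y,thumb,LF	CAT_Y:required,RecA_NT:required,CLAMP:typical	grp_UmuC	cterm_third	0.225	Pol V catalytic subunit type
DinP	Y	polymerase	Pol-core-Y,thumb,LF	CAT_Y:required,RecA_NT:absent	grp_DinP		0.225	no RecA-NT, no clamp motif
DinX	Y	polymerase	Pol-core-Y,thumb,LF,Tudor	CAT_Y:required,RecA_NT:absent,CLAMP:typical	grp_DinX	cterm_third	0.225	Tudor-bearing actinobacterial group
PolY-core	Y	polymerase	Pol-core-Y,thumb,LF	CAT_Y:required,RecA_NT:typical,CLAMP:typical	grp_PolY-core	cterm_third	0.225	DinB/Pol IV-like central group
YqjW	Y	polymerase	Pol-core-Y,thumb,LF	CAT_Y:required,RecA_NT:required,CLAMP:typical	grp_YqjW	cterm_third	0.225	YqjW/UvrX type (PolY2)
scDinB2-like	Y	polymerase	Pol-core-Y,thumb,LF	CAT_Y:absent,RecA_NT:required,CLAMP:typical	grp_scDinB2-like	cterm_third	0.225	Streptomyces inactive PolY (iPolY)
gbDinB2-like	Y	polymerase	Pol-core-Y,thumb,LF	CAT_Y:absent,RecA_NT:required,CLAMP:typical	grp_gbDinB2-like	cterm_third	0.225	G. bemidjiensis-type inactive PolY
ImuB1	Y	polymerase	Pol-core-Y,thumb,LF,ImuB-C	CAT_Y:absent,RecA_NT:required,CLAMP:typical	grp_ImuB1	cterm_third	0.225	proteobacterial ImuB
ImuB2	Y	polymerase	Pol-core-Y,thumb,LF,ImuB-C	CAT_Y:absent,RecA_NT:required,CLAMP:typical	grp_ImuB2	cterm_third	0.225	actinobacterial ImuB
ImuBx	Y	polymerase	Pol-core-Y,thumb,LF,ImuB-C	CAT_Y:absent,RecA_NT:required,CLAMP:typical	grp_ImuBx	cterm_third	0.225	remaining ImuB-like sequences
.RecA	.	accessory	RecA-core		grp_.RecA		0.05	recombinase; mutasome scaffold
.ImuA	.	accessory	ImuA-core		grp_.ImuA		0.05	RecA homolog partnering ImuB-DnaE2
.UmuD	.	accessory	UmuD-core		grp_.UmuD		0.05	Pol V small subunit (UmuD' dimer)
.YqjX	.	accessory	YqjX-arm,YqjX-body		grp_.YqjX		0.05	YqjX/YolD small subunit, full length
.YqjX-NT	.	accessory	YqjX-arm		grp_.YqjX-NT		0.05	small subunit reduced to the N-terminal arm
.YhjD	.	accessory	YqjX-arm,YhjD-extra		grp_.YhjD		0.05	arm fused to an unrelated domain
.ImuBC-solo	.	accessory	ImuB-C		grp_.ImuBC-solo		0.05	standalone ImuB-C beta-barrel protein
.SRAP	.	accessory	SRAP-core		grp_.SRAP		0.05	SOS-response associated peptidase-like partner
.DnaQ-solo	.	accessory	DnaQ-exo	DEDDh:required	grp_.DnaQ-solo		0.05	standalone proofreading subunit (epsilon-like)
.DnaQ-like	.	accessory	DnaQ-exo	DEDDh:required	grp_.DnaQ-like		0.05	distant standalone DEDDh homolog, not a validated DnaQ
.FEN-solo	.	accessory	FEN-exo	FEN_AS:required	grp_.FEN-solo		0.05	standalone 5'-3' exonuclease complementing missing Pol I
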