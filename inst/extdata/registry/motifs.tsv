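motif_id	mode	domain_id	anchor_columns	pattern	profile_ref	threshold
PHP_AS	exact	PHP	5,7,21,23,41,43,56,61,66	H,H,D,H,E,H,C/H,D,H		NA
DEDDh	exact	DnaQ-exo	6,26,41,61,76	D,E,D,D,H		NA
DEDDy	exact	DnaQ-exo	6,26,41,61,76	D,E,D,D,Y		NA
FEN_AS	exact	FEN-exo	8,22,40,58,72	D,D/E,E,D,D		NA
CAT_A	exact	Pol-core-A	70,100,103	D,D,E		NA
CAT_B	exact	Pol-core-B	70,100,103	D,D,E		NA
CAT_Y	exact	Pol-core-Y	60,90,93	D,D,E		NA
CAT_C	exact	Pol-core-C	70,100,102	D,D,D		NA
CAT_X	exact	Pol-core-X	60,88,90	D,D,D		NA
CLAMP	regex	.		Q,x,x,L,F		NA
RecA_NT	profile	.			motif_RecA-NT	0.5
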