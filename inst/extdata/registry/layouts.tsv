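group_id	element	start	end
PolA1	FEN-exo	1	90
PolA1	LINKER	91	100
PolA1	DnaQ-exo	101	190
PolA1	LINKER	191	200
PolA1	Pol-core-A	201	380
PolA1-like	DnaQ-exo	1	90
PolA1-like	LINKER	91	100
PolA1-like	Pol-core-A	101	280
PolA2	PAD60	1	60
PolA2	DnaQ-exo	61	150
PolA2	LINKER	151	160
PolA2	Pol-core-A	161	340
PolA3	DnaQ-exo	1	90
PolA3	LINKER	91	100
PolA3	Pol-core-A	101	280
G1	PolB-NT	1	80
G1	LINKER	81	90
G1	DnaQ-exo	91	180
G1	LINKER	181	190
G1	Pol-core-B	191	370
G2	PolB-NT	1	80
G2	LINKER	81	90
G2	DnaQ-exo	91	180
G2	LINKER	181	190
G2	Pol-core-B	191	370
G3	PolB-NT	1	80
G3	LINKER	81	90
G3	DnaQ-exo	91	180
G3	LINKER	181	190
G3	Pol-core-B	191	370
G4	DnaQ-exo	1	90
G4	LINKER	91	100
G4	Pol-core-B	101	280
G5	DnaQ-exo	1	90
G5	LINKER	91	100
G5	Pol-core-B	101	280
G6	DnaQ-exo	1	90
G6	LINKER	91	100
G6	Pol-core-B	101	280
G7	DnaQ-exo	1	90
G7	LINKER	91	100
G7	Pol-core-B	101	280
G8	DnaQ-exo	1	90
G8	LINKER	91	100
G8	Pol-core-B	101	280
PolC	PHP	1	100
PolC	LINKER	101	110
PolC	DnaQ-exo	111	200
PolC	LINKER	201	210
PolC	Pol-core-C	211	390
DnaE1	PHP	1	100
DnaE1	LINKER	101	110
DnaE1	Pol-core-C	111	290
DnaE1	LINKER	291	300
DnaE1	OB	301	370
DnaE1	LINKER	371	380
DnaE1	CTD	381	440
DnaE3	PHP	1	100
DnaE3	LINKER	101	110
DnaE3	Pol-core-C	111	290
DnaE3	LINKER	291	300
DnaE3	OB	301	370
DnaE3	LINKER	371	380
DnaE3	CTD	381	440
DnaE2A	PHP	1	100
DnaE2A	LINKER	101	110
DnaE2A	Pol-core-C	111	290
DnaE2B	PHP	1	100
DnaE2B	LINKER	101	110
DnaE2B	Pol-core-C	111	290
DnaE2X	PHP	1	100
DnaE2X	LINKER	101	110
DnaE2X	Pol-core-C	111	290
PolX1	8kDa	1	60
PolX1	LINKER	61	70
PolX1	Pol-core-X	71	220
PolX1	LINKER	221	230
PolX1	PHP	231	330
PolX2	Pol-core-X	1	150
PolX2	LINKER	151	160
PolX2	CTD	161	220
PolX-like	PHP	1	100
UmuC	Pol-core-Y	1	150
UmuC	LINKER	151	160
UmuC	thumb	161	200
UmuC	LINKER	201	210
UmuC	LF	211	260
UmuC	CLAMP_LINKER	261	270
UmuC	RECA_SEG	271	290
DinP	Pol-core-Y	1	150
DinP	LINKER	151	160
DinP	thumb	161	200
DinP	LINKER	201	210
DinP	LF	211	260
DinP	LINKER	261	270
DinX	Pol-core-Y	1	150
DinX	LINKER	151	160
DinX	thumb	161	200
DinX	LINKER	201	210
DinX	LF	211	260
DinX	CLAMP_LINKER	261	270
DinX	Tudor	271	330
PolY-core	Pol-core-Y	1	150
PolY-core	LINKER	151	160
PolY-core	thumb	161	200
PolY-core	LINKER	201	210
PolY-core	LF	211	260
PolY-core	CLAMP_LINKER	261	270
PolY-core	RECA_SEG	271	290
YqjW	Pol-core-Y	1	150
YqjW	LINKER	151	160
YqjW	thumb	161	200
YqjW	LINKER	201	210
YqjW	LF	211	260
YqjW	CLAMP_LINKER	261	270
YqjW	RECA_SEG	271	290
scDinB2-like	Pol-core-Y	1	150
scDinB2-like	LINKER	151	160
scDinB2-like	thumb	161	200
scDinB2-like	LINKER	201	210
scDinB2-like	LF	211	260
scDinB2-like	CLAMP_LINKER	261	270
scDinB2-like	RECA_SEG	271	290
gbDinB2-like	Pol-core-Y	1	150
gbDinB2-like	LINKER	151	160
gbDinB2-like	thumb	161	200
gbDinB2-like	LINKER	201	210
gbDinB2-like	LF	211	260
gbDinB2-like	CLAMP_LINKER	261	270
gbDinB2-like	RECA_SEG	271	290
ImuB1	Pol-core-Y	1	150
ImuB1	LINKER	151	160
ImuB1	thumb	161	200
ImuB1	LINKER	201	210
ImuB1	LF	211	260
ImuB1	CLAMP_LINKER	261	270
ImuB1	RECA_SEG	271	290
ImuB1	ImuB-C	291	360
ImuB2	Pol-core-Y	1	150
ImuB2	LINKER	151	160
ImuB2	thumb	161	200
ImuB2	LINKER	201	210
ImuB2	LF	211	260
ImuB2	CLAMP_LINKER	261	270
ImuB2	RECA_SEG	271	290
ImuB2	ImuB-C	291	360
ImuBx	Pol-core-Y	1	150
ImuBx	LINKER	151	160
ImuBx	thumb	161	200
ImuBx	LINKER	201	210
ImuBx	LF	211	260
ImuBx	CLAMP_LINKER	261	270
ImuBx	RECA_SEG	271	290
ImuBx	ImuB-C	291	360
.RecA	RECA_SEG	1	20
.RecA	RecA-core	21	140
.ImuA	ImuA-core	1	120
.UmuD	UmuD-core	1	70
.YqjX	YqjX-arm	1	30
.YqjX	LINKER	31	40
.YqjX	YqjX-body	41	100
.YqjX-NT	YqjX-arm	1	30
.YhjD	YqjX-arm	1	30
.YhjD	LINKER	31	40
.YhjD	YhjD-extra	41	100
.ImuBC-solo	ImuB-C	1	70
.SRAP	SRAP-core	1	80
.DnaQ-solo	DnaQ-exo	1	90
.DnaQ-like	DnaQ-exo	1	90
.FEN-solo	FEN-exo	1	90
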