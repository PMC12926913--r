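complex_id	priority	required_components	variants	known	notes
DnaE2X-iPolY-ImuBC-RecA	1	dnae2=DnaE2X;poly=recA_NT+inactive+-imuBC;imubc;reca		FALSE	split-ImuB system; candidate ancestor of ImuA-ImuB-DnaE2
ImuA-ImuB-DnaE2	2	dnae2=DnaE2A;imua;poly=ImuB1|ImuB2|ImuBx+recA_NT+inactive+imuBC		TRUE	previously characterized mutasome
DnaE2B-PolY-ImuBC-RecA	3	dnae2=DnaE2B;poly=recA_NT+active;imubc;reca		FALSE	active PolY plus standalone ImuB-C
DnaE2B-iPolY-RecA	4	dnae2=DnaE2B;poly=recA_NT+inactive+-imuBC;reca	scDinB2-like,gbDinB2-like	FALSE	two iPolY flavors encoded as variants of one type
DnaE2B-PolY-RecA	5	dnae2=DnaE2B;poly=recA_NT+active;reca		FALSE	Bacteroidetes-type system
DnaE2B-ImuBC	6	dnae2=DnaE2B;imubc		FALSE	DnaE2B with only an ImuB-C partner
UmuC-UmuD2-RecA	7	poly=UmuC+recA_NT+active;umud;reca		TRUE	Pol V; previously characterized mutasome
YqjW-YqjX-RecA	8	poly=YqjW+recA_NT+active;small_subunit=.YqjX|.YqjX-NT|.YhjD;reca	.YqjX,.YqjX-NT,.YhjD	FALSE	three small-subunit variants linked by the N-terminal arm
UmuC-SRAP	9	poly=UmuC;srap		FALSE	UmuC-like polymerase with SRAP-like partner
PolY-ImuBC	10	poly=active;imubc		FALSE	PolY with standalone ImuB-C
PolY-RecA	11	poly=recA_NT;reca		FALSE	ancestral-type dimer; most abundant; lowest priority fallback
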