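domain_id	reference_alignment	min_hit_length	len
Pol-core-A	dom_Pol-core-A	90	180
Pol-core-B	dom_Pol-core-B	90	180
Pol-core-C	dom_Pol-core-C	90	180
Pol-core-X	dom_Pol-core-X	75	150
Pol-core-Y	dom_Pol-core-Y	75	150
PHP	dom_PHP	50	100
DnaQ-exo	dom_DnaQ-exo	45	90
FEN-exo	dom_FEN-exo	45	90
8kDa	dom_8kDa	30	60
OB	dom_OB	35	70
CTD	dom_CTD	30	60
Tudor	dom_Tudor	30	60
ImuB-C	dom_ImuB-C	35	70
LF	dom_LF	25	50
thumb	dom_thumb	20	40
PolB-NT	dom_PolB-NT	40	80
RecA-core	dom_RecA-core	60	120
ImuA-core	dom_ImuA-core	60	120
UmuD-core	dom_UmuD-core	35	70
YqjX-arm	dom_YqjX-arm	20	30
YqjX-body	dom_YqjX-body	30	60
YhjD-extra	dom_YhjD-extra	30	60
SRAP-core	dom_SRAP-core	40	80
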