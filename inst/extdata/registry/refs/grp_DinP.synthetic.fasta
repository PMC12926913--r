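>DinP_anchor1
NLVITAFELINITLSNNIDLLTITMFEYPGMAKPGREELDSEEENTSMQEEQLRPPDKSDGAGVVARPFMKSVELREQCD
LTLQTRGNGDPEEYCGTHAPWPKLEELQREEIQEGKPRNPPKFETNVVLLFESNGCIITLPTDFSRVDSRSAPTYGGTPE
FSKVDAEGNEQTGHSSGGRPLNLGYNEAKDIKTYNDGQFIEPKLRINFAPGIAARLLTENYEDAQHPGFEKIDGQIESFD
AWPRWLRQISDEFVFRRPDEMRASFADLFD
>DinP_anchor2
NLVITAFELINITLSNNRDLLTITMFEYPGAAKPGREELDSEEEDTSMQEEQLRTPDKSDGAGVVARLFMKSVELREQCD
LGLQTRGNGDPEEYCFTHAPWTKLEELQRVEIQEGKPRNPPKFETNVVLLFESNGCIITLPTEFSRVDSQSAPTYGGDPE
FSKVDAEGNEQTGHSSGERPLNLGYNEAKDIKTYNDGQFIEPKLVINFAPGIAARLLTENYEDAQHPGFGKIDGQIESLE
AWPRELRQISDEFVFRRPDEMRASFADLFD
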