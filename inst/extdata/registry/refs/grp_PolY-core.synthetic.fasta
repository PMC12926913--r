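>PolY-core_anchor1
NLVIRPEELINITNTNSEDGLKINILESWRMAKPGYEELYQEKENPSLQGFGLDPPDKSDGEGVFLRPDMNTIELSEKPD
LLDQTVKNSDPLEGSETHAPDMKLEEPHREQIQEFKATNFPKVLENVVLLFEGKGCVITLPTDFMRVCSEESKPEGEFIF
FPKEDSDGETEILHSMGGIPLPSGYDNAPDIKTKNDKQFEGADTVKKSIIGWVTRKGTTNSADAQHPEVEKITDQIEWFD
ALSRDLAQPSDPNFFNRIDEKGQSSLFAPTDHRIVKRLNIFPKNKERLAS
>PolY-core_anchor2
NLVIRPEELINITNTNSEDGLKINILESWRMAKPGYEELYQEKENPSLQCFGLGPPDESDGEGVFLRPDMNTIELSEKPD
LLDQTVKNSDPLEGSETHAPDMKLEGPHREQIQEFKATNFPKVPENVVLLFEGKGCVITLPTDFMRVCSEESKPEGEFIF
FPKEDSDGETEILHSMGGIPLPSGYDNAPDIKTKNDKQFEGADTVKKSIIGWVTRKGTNNSADAQHIEVEKITDQIEWFD
ALSRDLAQPIDPNFFNREDEKYQSSLFAPTDHRIVKRLNIFPKNKERLAS
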