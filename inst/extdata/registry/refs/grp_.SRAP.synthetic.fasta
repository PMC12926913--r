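>.SRAP_anchor1
AFQWGTKKLASNNRLQMSHGRCSQESLDVGTPWVGVDTKEQPSGLKLTTERLSNPFIGTAGCLLKTDLESLASAFGVGGA
>.SRAP_anchor2
AFQWGTKKLCSNNRLQMSHGRCSQESLDVGTPWVGVDTKEQPSGLKLTTERLSNPRIGTAGCLLKTKLESEASAFGVGGA
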