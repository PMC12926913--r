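>YqjW_anchor1
NLVITAFELINITNFTSEDCLKITIDESEDMAKVGRFELYMLESNPGLQKPGLDPPDNSDQEGEFAFPDMKSVERFEQPD
LLKQTTKSSDPEEGRGGHAPWGKLPEEGRRLIQQVKVTNRPKQETNVVLLFPLNGHIITLPTEFSRVDSRSNVHYQLDIF
FCKVDSRGETENDHLAGGRPLPFGYNNAPDIKTIWDGQALPEEMLLKAPKGQYTKELAENSWFAQHPEFEPADRQIESFY
AIKPWLAGVKDPYVFRRIDEPPQSSLFGEVDHRIVKRLNIFPKNKERLAS
>YqjW_anchor2
VLVITAFELINITNFTSEDCLKITIDESEDMAKVGRFELYMLESNPGLQKPGLDPPDNSDQEGEFAFPDMKSVERFEQPD
LLKRTTKSSDPSEGVGGHAPWGSLPEEGRRLIQQVKVTNRPKQEMNVVLLFPLNIHIITLPTEFSRVDSRSDVHYQLDIF
FCKVDLRGEQENDHLAGGRPLPFGYNNAPDIKTIWDGQALPEEPLTKADKGQYTKELAENSWFAQHPEFEPADRQIESAY
AIKPWLAGVKDPYVFRRIDEPPQSSLFGESDHRIVKRLNIFPKNKERLAS
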