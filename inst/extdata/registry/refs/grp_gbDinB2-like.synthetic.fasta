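>gbDinB2-like_anchor1
NLVITAIELINIANFNNEDGLKITILESPDMPKPMREELYMEDEGPSLQGEGLDPPGKGDPEGVFDRPDMKGVELREQPD
LLKQTRGNSNPEEGRGTHAPWEDLEESLREEIQTFKATNVPPFETHSVLLFVLLDCIITIPTIFSQVDSRDEQEAGQLSG
FSKVDNAGETENDMSMPGLPLLVLYINAPDIKYYNDGFAIRKSFSSPGLDGHNTRQETGESEDAQHPDFGKIDDQIESFD
AWDRWADDVSDPFVFRRRDKGVQSSLFKSWDHRIVKRLNIFPKSKERLAH
>gbDinB2-like_anchor2
NLVITAIELINISNFNNEDGLKITILEKNDMPKPMREELYMEDEGPSLQGEGLDPQGKGDPEGVFDPPDMKGVFLREQPD
LLKQTRGNSNPEEGRGTHAPWEDLEESLREERQTFKATNVPPFETHSVLLFVLLDCIITIPTIFSQVDSRDEQEAGQLSG
FSKVDNAGETENDMSMPGLPLLVLYINAPQIKYYNDGFAIRKSFSSPGLDGHNTRLETGESEDAQHPDFGKIDDQIRSFD
AWDRWADDRSDPFVFRRRDKGVQSSLFKSWDHRIVKRLNIFPKSKERLAH
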