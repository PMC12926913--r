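>scDinB2-like_anchor1
NLVIEAFELYNITNFNPHDSLKITILRTDDMAKWGREEIYMHPINPRSQGEAGDPPDKSDPENVFSRPDMKGVELSEQPY
HLSTPRKNLNAEEGRKGKAPWMKLEEELRHEIQEFKATNVPMIFDNEVLLFELNMCIITLPTDFPRVDNFTFNNSLLAVV
FSKSDSRLNTNNDHSMGGRQLPFGYNNAPDIKTYNDGQADGFPHPVDQCPGHNTRLLTENSYDAQHCGREVIDDQIERED
AWMRWLAQVSDEFVFRRIDELMQSSLFQRRDHRIVKRLNIFTKNKERLAS
>scDinB2-like_anchor2
NLVIEAFELTNITNFNPHDSLKITILRTDDMAKWGREEVYMHPINPRSQGEARDPPDKSDPENVFSGPDVKGVYLSEQPY
HLSTPRKNLNAEEGRKWKAFWMKLEEELRHEIQEFKATNVPMPFDNEVLLFRLRMCIITLPTDFPRADNFTFNISLLAVV
RSKSDSRLNHNNDHSMGGRQLPFGYNNAPDIKTYNDGQADGFPHPVDQCPGHNTRLLTENSYDAQHCGREVIDDQIELKH
AWMRWLAQVSDEFVFPRFDELMQSSLFQRRDHRIVKRLNIFTKNKERLAS
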