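>consensus
NLVITAFELINITNFNSEDGLKITILESPDMAKPGREELYMEEENPSLQGEGLDPPDKSDGEGVFARPDMKGVELREQPD
LLKQTRKNSDPEEGRGTHAPWMKLEEELREEIQEFKATNVPKFETNVVLLFELNGCIITLPTDFSRVDSR
>var1
NLVITAFEAINITNFNSPDGLKITILESPDMAKPGREVLYREECNPSLQGEGLDPPDKSDGEGVFARPDMKGEEHREQPE
LLKQTRKNSDPEEGRGTPAPWMNLEEELREEIQEFKATNVPKFETNVVHLFFLNGCDITLVTDFSRVDSR
>var2
NLMITFFELINITNFISEDGLKITILESPDMAKPGREELYMEEEQPSLQGEGTDPPDKSDGEGVFARPDMKGVELREQPD
LLKQTRKNSDPTEGRGTHAPWMKLEESLREEITEFKATNNPKFETNVVLLFELNGCIITLPTDFSRVDSF
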