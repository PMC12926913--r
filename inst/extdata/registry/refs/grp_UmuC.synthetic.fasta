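>UmuC_anchor1
NLVITEFELINITNFNQEDGLVIDILESPDMAKSGRMELYMEESNPSLQMEGLDPPDKSDGEGVFNQPAMLGVELREQPD
LLKQTRENSDPEEGCGTHAPWMKLEEELQEEIQEFKGVNDPKFKTNVVRPFELNGCIITLPTDKSRVGSRELHEIRSYSL
PSLVDSRGEDEESHVMGGRPQPFGYNNAEDFKTYNAGQAIYSISDAAHKGGHNTRLPTLDSGDAQHSGFIKIDVQPESFA
AWDRWLAQVSRPFVFRRTNEVKQSSLFAWNDHRIVKRLNIFPKNKERLAS
>UmuC_anchor2
NLVITEFELINITNFNSEDGLVIDILESPDMAKSGRMELYMEESNPSLQMEGLDPPDKSDGEGVFNQPAMLGVELREQPD
LLKQTRENSDPEEGCGTHAQWMKLEEELQERIQEFKGVNRPKFLTNNVRPFELNGCIITLPTDKSREGSRELHEIRSYSL
PSLVDSGGEDEESHVAGGRPQPFGYNNAEDFKTYAAKQKITSISDAAHKGGHNTRDPTLDSGDAQHRGFIKIDVQPESFA
AWDRWLAQVSRPFVFRRTNEVKQSSLFAWNDHRIVKRLNIFPKNKERLAS
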