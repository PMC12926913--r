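>ImuBx_anchor1
NLVITQFEGVNFTNDNSEDGLPITIDEKPGMPKPGDWELYMEEENPSLQGEGLDTPDKPDGEGAFARDDMKGCELREQND
LLKQTRKNSNPEEGRHYHLGWMKLEEELKEFIQEFHATNSPKLETNVVLLFALNMCIITSPTDFSRVSYRRNRESQAHLE
FAKVDARGMQENDHAMGGRTLPFGYVNAPDCKTSNDGQAISLKTTFNYTMGHNTRLLTEPSEDAQHPGFEKIDDQIEGFD
LWDAWPAQVSDPFSFRRIDGEMQSSLFSFADHRIVIRLLYFPKNKERLASNNQSGPLTRCEHDVSVFKMIWILSIHLDAI
KNNSGPGITKQFGNDIFAGTAEIFHVIVLPQDLLYINALK
>ImuBx_anchor2
NLVITQFEGVNFTNDNSEPGLPITIDEKPGMPKPGDWELYMEEENPSLFGEGLDMPDKPDGEGAFARDDMKGCELREQID
LLKQTRKNSNPEEGIHYKPGNMKLEEELKEFIQEFHATNSPKLETNVVLLFILNMCIITSPTDGSRVSYRTNRESQAHLE
FAKVSARGMQENDHAMGGRTLPFGYVNAPDCKTSNDGQAISLKTTFNYTMGHNTRLLTEPSEDAQHPGFEKIDDQIEGFD
LWDAWPKQVSDPFSFRRADGEMQSSLFSFADHRIVIRLLYFPKNKERLASNNQSGPLTRCEHDVSVFLMIWILSIHLDAI
KNNSGPGIEKQFGNDIFAGTAEIFHVIVLPQDLLYINELK
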