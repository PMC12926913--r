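>ImuB2_anchor1
NPVITAVKLIEGTGLNLEDGLPIVFLESTDMDKWLVEELYSEEENPSLQGEGGDPPDKSDGELVHARPDPKGCELREQTD
HLKQELKNENPEEGRKTHAPVMKIEEELREEIQEFFATNVPKFEINVVLLFPALGCIITLPPLFLRDDWRNSGYVGYGMK
FYKSDNGGETDNDHHKEGIPLTLGVNNAPRNKTHCDGQAILVYSHLEVTGGMKWRPHDENSELKQHPGFVKIDDQIESFD
LMDRWLAQQSDPFVFRRIVEDPQSSLFSGEDQRIVKRLNVFPKNKERLASTNQPGPLERCEHDVSYAKMNRIKSIHLMAA
TNNCSPGIDKQQGRSIFAGGLEIFHSIMLFQDLLYINKLK
>ImuB2_anchor2
NPVITAVKLIEGTGLNLEDGLPIVFLESTDMDKWLVENLYSEEENPSLQGEGGDPEDKSDGELVHARPDPKGCELREQTD
HLKQELKNENPEEGRKTHAPVMKIGEELREEIQEFFATNAPKFEINVVLLFPALGCIITLPPLFLRDDWRNSGYVGYGMK
FYKEDNGGETDNDHHKESIPLTLGVNNAPRNKTHCDGQAILVYSHLEKTGGMKWRPHDENSELKQHPGFVKIRDQIESFD
LMDRWLAQQSDPFVFRRIVEDPQSSLFSGEDQRIVKRLNVFPKNKERLASTVQPGPLERCEHDVSDAKMNRIVSIHLMAP
TNNCSPKIDKQQGRQIFAGGLEAFHSIMLFQEQLYINKLK
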