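>DnaE2X_anchor1
GNLVHNHSIVMASLYCVTPDDLHVVKTFCDEKAVAPHCEPNVHFFTNITENLAIECLNAGDLGSSHVNAIVAFKALANMD
MLAWLEALAVPEKLHLCAMAVSLMHKAPSDLLSFGAIEGTRYFSKDYWAPLRLAFSLCNKFHIWIEVYLVSSLLNLYPPQ
MTVLEGTDCFYSHLPIGSPDHKMCVSSYDSYTSVSPDSTESSNLRLTGHDVDLDTTTLPEANVGPLTIKTRTPGFENGTV
PWREEPGWIRVWFLADVLLLMGELAFFFEVEPARLCRKPPLAAAGNAYGS
>DnaE2X_anchor2
GNLVHNHSIVMASLYCVTPDDLHYVKTFCDEKAVAPHCEPNVHFFTNITENLAAECLNAKDLGSSHVNDIVAFKALAYMD
MLAWLEALAVPETLHLCFMAVSLMHKAPSDLLSFGAIEGTRYFSKDYWAPLRLAFSLCNKFHIWIEVYLVSSLLNLYPPQ
MTVLEGTDCFYSHLPIGSPDHKMCVSSYDEYTSVSPDSTESSNLRLTGHDVDLDTTTLPEANVGPLTIKTRDPGFENGTV
PWREEPGWIRVWFLADVLLLMGELAFFFEVEPARLCRKPPLAAAGNYYGS
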