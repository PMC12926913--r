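>G5_anchor1
PEDNRDCLQHDAVANICKLSLTPIVEQSFKTWTKQETLIFDLMTGGLEVEWFLGSPEGLYDFYETAMTTSNGDAVYAFGG
FEKKRLRLGPLCVDPPRAQVRNTARRVEGFGVSDLRRATNLYAGQAQYSEIARIRLDHTFAVGSSSPHDHKADLVCPIGS
KYYFIVVLIDLVTQFTDSKVTGMNTRKDVDNMVAIVVDSDLDENPVPPQLFDSTLQYTSERVKEREKTDGSVCSIISGKA
CLCYKALFAITDTLDHLLGSHAILVGVPSFAVADKFEIGK
>G5_anchor2
PEDNRDCAQHDAVANHCKFSLTPIVEQSFKEWTKQETLIFDLMTGGLEVEWFLGSPEGLYDFYETAMTTSSKDAVYAFGG
SEKKRLRLGPLCVDPPRAQVRNTLQRVEGFGVSDLRRATNLYAGQAQDSEIAYIRLDKTFAVGASSPHDKKADLVCPIGS
KYYFIVVLIDLVYQFTDSKVTGMNTRKDVDNMVAIVSDSDLDENPAPPQLFDSTLQFASERVKEREKVDGSVCSFISGKE
CLCYKALFAWTDTLDHLLGSHAILVGVPSFAVATKFEIGK
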