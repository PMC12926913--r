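>consensus
VYELFCTYLRSEKNLEVDPMRLESMAGQDPKVPSRISVNKASCPAAGVIDVISDELLWRFVMMADVGKVHEEHIVSEETK
TVLTYWSWACVMSIFPASMELQSYFVDCGYPLNTRPIDTT
>var1
VYELFCTYLRSEKNLEVDPMRLEDMAGQDPKVPSRISVNKASCPAAGVIDVISFELDWRFVCMADVGKVHEEHIVSEEEK
AVLTYWSWSCVMSIFAASTELQSYFVKCGYPLNARPIDTT
>var2
VYELFCTYLRKEKNLEVDPMRLESMAGQDPKVPSRISVNLAHCPAAGVIDVISDELLWRKVMMAVVGKVHEEHVVSEATK
TVLTYWVWACVMSIFPASMLLQSYFVDCGYPLNTRTIDTT
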