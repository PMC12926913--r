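>.RecA_anchor1
DHRIVKRLNIFYKNKERLASVYELFCTYLRSEKNLEVDDMRLESMAGQDPKVPSRISVLKASCPAAAVIDVISDEELWRF
VMMAQVGKVHEEHIVSEETKTVLTYWSWACVMSVFPASMELQSYFVDCGYPLNTRPIDDT
>.RecA_anchor2
DHRIVKRLNIFYKNKERLASVYELFCTYLRSEKNLEVDDMRLDSMAGQDPKVPSRISVLKSSCNAAAVIDVISDEESWRF
VMMAQVGKVHEEHIVSEETKTVLTYWSSACVMSVFPASKELQSYFVDCGYPLNTRPIDDT
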