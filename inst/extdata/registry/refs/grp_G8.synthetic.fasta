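>G8_anchor1
MNSNRDRRQHDTVFNICKLSLTPEKEYSFKKTTQQETLEFDWMYGGPIVEWFLGSPEGKYDFYIGAMTTSNGAAVYANES
LVNKRLRFGIPCNILAQAAENNTARRVEHMGVSDLSLMTKITKQQWQYSEHPRIVLDHASAVGSGSAHDDLNDLVCICGM
KYPFIVVLNDESTTGRDSTVTGMVYRKDVDNKGRHHVVSDLDEDSVVPQLFDSFGQYQNEPDKIVELTDGSVCAIISRCI
CVKEKKLLAYTDTGLYGLGSVAILVDVPGFAVADNFEIGW
>G8_anchor2
MNSNRDRRQHDTVFNICKLSLTPEKEYSFKKTTQQETLFFDWMYAGPIVEWFLGNPEGKYDFDIEAMTTSSGAAVYANES
LVNKRLRFGKPCNILAQAAENNTARRVEHMGVSDLSLMTKITLQQWCYSEHPRIVLDHVSAVGSGSAHDDLNDLVTICGM
ALPFIVVLNDESRTGRDSTVTGMVDRKDVDNKGRHHVVSDLDELSVVPQLFDSFGQYQNEPDKIVELTDGSVCAIISRCI
CVKEKKLLAYTDTGLYGLGSVAILVDVPGFAVADNFEISW
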