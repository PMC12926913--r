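>PolA1-like_anchor1
MESNRDRRQHWSTANIIKLSLLPMKEESFKRWTQQETLEFDWMYQFGEKEEFGGSPELKYDFTATAQTTSNKDAVYAKES
FELKRLAHGSIKVERAATLVATASSSRPDFVNKRKLAERPMYTLNGSCSNGQKTHLTLTVIAKSAAAKRYQYLCKIQKQL
LGPDFYELLDSAGKALFDNLVADDSHSRPTAKDVILSDKDVNEALRSHKLDTIEWRIQTFSMDNSANQTQNKNFEDLTME
AIVVNELNDRMEVIRGYPGQPPELGLQCITALTLNEVEPT
>PolA1-like_anchor2
MESNYDRRQHWSTANIIKLSLLPMKEEERKRWTQQETLEFDWMYGFGLKEEFGGSPELKYDFTATIQTTSNKDAVYAKES
FELKRLAHGSIKVERAAALVATASSSRPDFVNKRVLAERPMYTLNGSCSNGQITHLTLTVIAKSAAAKRYQYLCKIQKEL
LGPDFYELLDCAGKALFDNLVADDSLSRPTAIDVILSDKDVNEALRSHKADTIEWRIQTFSMDNSANQTQNKNFEDVTME
AIPVNELNDRMEVIRGYPGQPPELGLQCITALTLNEVEPT
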