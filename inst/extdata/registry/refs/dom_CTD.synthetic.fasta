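>consensus
DFETQLKARKTKESKIRRFGPRFVFSLTPDYKRTVQMQWNSIIAFQWYNGGGKTPESPVG
>var1
DFETQLQARKTKESKIRRFGPREFFSRTPDYKRTVQLQWKSIIAFQWYNGGGKTPESPVG
>var2
DFETQLKARKTKESKIRRFGPRFVFSLTPDYKRTVKMQANSIIAFQWYNGGGKTLESPVK
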