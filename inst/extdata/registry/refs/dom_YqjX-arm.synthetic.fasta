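>consensus
YTQSRVRKGVGKVGWYLQDKDFHVAGAGGG
>var1
YTQSRVRKGVGKVAWYLQDKDFHVAGNGGG
>var2
YTQIRVRKGVGKVGWYLQDKDPHVAGAGEG
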