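>consensus
FSKVDSRGETENDHSMGGRPLPFGYNNAPDIKTYNDGQAI
>var1
FSKVDSRGETENDHSMGGRPLPFGKNNAPDIKTYNDGQAI
>var2
FSKVDSRGETENDHSMGGRPLPFGYNNAPDIKDYNDGQSI
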