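>consensus
KKPHCDNDAEQVRVSKLDHESAQGSVFSDAENSTRDSGPAASNQKIKPKCSQVRRMANPF
>var1
KKPHCDNDAEQVRVSKLDHESAQGSVFSDAENSTRDSGPAAENQKIKPKCSQVRRMANPF
>var2
KKPTCDNDAEQPRVSKLDHESAQGSVFSDAEESTRSSGPAASNQKIKPKLSQVRRMANPL
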