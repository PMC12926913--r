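>.YhjD_anchor1
YTQSRNRKGVGKVNWYLQDKDFVVAGAGGALRKHSDGADVKKPHCDNDAEQVRVSKLDHESAQGSVFSDAENSTRDSGPA
ASNEKIKPKHSQVRRMANPF
>.YhjD_anchor2
YTQSRNRKGVGQVNWYLQDKDFVVAGAAGALRKHQDGADVKKPHCDNDAEPVRVLVLDHESAQGSVFSDAENSTRDSGRF
ASNEKIKPKHSQVRRMANPF
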