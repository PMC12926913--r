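>.FEN-solo_anchor1
WPTVQGSDEDGGAYLILCTTADVDKTRRNTKSNKNALPFEDEEPGRNPLIVPLRWALDNEAKIVRKDSQCADALSVTFDD
SMGILVIYLF
>.FEN-solo_anchor2
WPTVQGSDEDGGAYLILCTTADVDKTRVNTKSNKNELPFEDEEPGRNPLIVPLRWALDNEAVIVRPDSQCADALSVTFDD
SMGILVIYLF
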