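>DnaE2A_anchor1
GLLVHTHSIEMASLYPQIPDDLHVVLSPSDEKAVAEHCESNIHFFTNIGVVLADECLMAGDHMSYHVGAKAPPKALADMD
MTAWTEGIKVSEKNKLCAMIDEGMNAPTSRLLMFAVIELGLYASKDTWAWRRLAFSLPNKFGAWIEDYVVSSRVNSYQPQ
MTGLEGADCFRIHYPIGSGDNKMCTSSYDLEIKVSPDTTESSYLRLTDNDVDLKTTRLPFDNVGLLAALWRTPGFENGSV
PWLAEVGDIKSWFLADVLLLMVELAFFDENENATLCNNVDPAVAGNARGG
>DnaE2A_anchor2
GLLVHTHSIEMASDYPQIPDDLHVVLSPSDEKAVAEHCESNIHFFTNIGVVLFDECLMAVDHMSYHVGQKAPPKALADMD
MTAWVEGQKVSEKNKLCAMIDEGMNAPTSGLLMFAVIELGLYASKDTWAWRRLAFSLPNKKGAWIKDYVVSSRVNSYQPQ
CTGLEGADCFRIHYPIGSGDNKMCTSSYDLEIKVSPDTTESSYLRLTDNDADLKGTRLPFDNVLLLAALWRTPGFENGSV
PWLAEHGEIKSWFLADVLLLMVELAFFDENENATLCNNVDPAVKGNARGG
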