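>consensus
DFVKDFRLHFPKEMQGQWKYAPVRYGADVYSEDSSFSVEVNIPQGGWGDAAIELFWCSHWYASFTPDAFH
>var1
DFVKDFRLHFPKEMQGQWKYAPVRYGADAYYEDSSFSVEVNIPQGGWGDAAIELFWRSHWYANFTPDAFH
>var2
DFVKDFRLHFPFEMQGQWKKAPKRYMADWSSEDSSISVEVNIPQEGWGDAAIELFWCSHWYASFTPDAFH
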