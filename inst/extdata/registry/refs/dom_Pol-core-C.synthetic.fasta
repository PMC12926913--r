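>consensus
LLMFAVIETTLYASKDYWAWRRLAFALCNKFGIWIEDYVVSSLYNSYQPQMTVLEGADCFSIHYPIGSCDHKMCRSSYDS
YTYVSPDSTESPYLRLTGNDVDLKTTRLPEANVGPLTILGRTPGFENGSVPWRAEVGDIRVWFLADVLLLMGELAFFFEV
EPATLCRKVPPAVAGNARGQ
>var1
LLMFAVIETTLLASKDYWGIRRLAFALCNYFGIWIEDYVVSSLYNSYQPQMTVLEGADCCSIHYAIGSCDHKMCRSLYDS
YTYVHPDSTESPYLRLTGNDVDLFTTRLPEANVGPLTILGRTPGFENGSVPWRAELGDQRVWFLADVLLLMGELAFFFIV
EPATLCRKVPPDVAGFARGQ
>var2
LLMFAVIETTLYASKDYWEWRRLAFAGCNKFGISPEDYVVSSLYNSYQPQMTVLEGADCFSIHYPIDSCDHKMCRSSYDS
ITYVSPDSTESPYLLLTGNDVDLKTTTLPEANVGPLTILGRTPGFENHSVPWRAEVGDIRVWFLADNKLLMDELAFFFEV
EPATLCRKVPPAVIGNARGQ
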