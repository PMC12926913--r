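>.DnaQ-like_anchor1
MEPVSDRRQSVFLAEISQELSCKIVEGSYCKRDCTLAVFFDEMDYGLNVEEKLGSLEPKLDVYMTLMITGQNIAGYASNS
FGRHRLGFAI
>.DnaQ-like_anchor2
MEPVGDRRQSVFLAEISQELSCKIVEGSYCKRDCTLAVFFDSMDYGLNVEEKLGQLEPKKDVYMTLMITGQNIAGYASNS
FGRHRLGFAN
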