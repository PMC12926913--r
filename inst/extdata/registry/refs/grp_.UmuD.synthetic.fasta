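>.UmuD_anchor1
YSGQVSCGTGQCAMATLIMDSTPPNAPASAGPFFRNLVAIKYYEDWFGPLSQRNATTIVAVERRVLGFPE
>.UmuD_anchor2
YSGQVSCGTGQCAFATPIMDSTPNNAPASAGPFFTNLVAITYYEDWFGPLSQRNATTIVAVSRRVLGFPE
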