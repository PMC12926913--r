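family_id	fold_class
A	Klenow-fold
B	Klenow-fold
C	Polb-like
X	Polb-like
Y	Klenow-fold
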