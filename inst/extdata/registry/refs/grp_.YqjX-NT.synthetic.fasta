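>.YqjX-NT_anchor1
YTQSRVRKGVGKVGWYLQDKRFHVKGKGGG
>.YqjX-NT_anchor2
YTQSRVRKGVGKVGWYLQDKRFHYKGKGGG
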