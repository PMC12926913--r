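>DnaE3_anchor1
GTVVHTHSGVLTSLYEQTPDDLHVFKTPSDEKAVAPHCLSNVHFDTGRTLNLFIECLNAKDHFYSHVGAIAAPAALAYMD
MTAWGEGIAAPEKLHLCAMIYLQLSDTAKPLPMFAVIETTLYASKDYWAWDRLLFEHCRKFGGWPTAEVVSSLYNSYQPQ
FIVLEGDDCFPIHYPIGSPDAKMIRSSYDSYTYVSPDSTENGYLRLTGNDVDLGTTDLPEANPVNLTILGRTPGFERGSV
RWRAEVGDIRVWFQARVLCDMGELAFFFEVEPATLCRKVPPAVAGGNRGQMGLARSALEGDLVKDVRNHFPKEQQNQWKY
LPVSYMADVYSEDSSFSHTVNIDKGGWGDAAIEPFWCSLWYASFEALAFFDSQRCAAIKQDFETQLLARKTWESKGRRFG
FDFVFSLTPDTKDTVQMQWNSIISFQWKPEGGKGPESPKM
>DnaE3_anchor2
GTVVHTHSGVLSSLSEQTPDDLHVFKTPSMEKAVAPHCLSNVHFDTGRTLNLFIECLNAKDHFYSHVGAIAAPAALAYPD
MTAWGEGIAAPEKLHLKAMIYLQLSDTAKPLPMTAVIETTLYASKDYWAWTRLLFDHCRKFGGWPTAELVSSLYNSYQPQ
FIVLEGDDCFPIHYPIGSPDAKMIRSSYDSYTYVSPDSTENGYLRLTGNDVDLGTTDLPEANPVNLTILGRTPGFERGSV
RWRAEVGDIRVWFQARVLCDMGELAFFFEVEMATLCRKVPPAVAGGNRTQMGLARSALEGDLVKDVRNHFLSEQQNQWKY
LPVSRMADVYSEDSSESHTDNIDKGGWGDAAIEPFWCSLWYASFEALAFFDSQRCAAIKQDFESQLGARKTWESKGRRFG
FDFVFSLTPDDKDTVQMQNNSIISFQWKPEGGKGPESPKM
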