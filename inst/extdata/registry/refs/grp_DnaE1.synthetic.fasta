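>DnaE1_anchor1
GNLVHTHSIVMASLYEQTPDDLHVLKTPSTEKQNAPQGESEAHFFTNITENLAIICLNAGDHPDSHVGPIAAPKALANMD
MTAWLEGIAVPEKLNTEAVILVIQFSYIQYLLMFAVIETSEQRKDDSEAVRRLAHALCAKGGIDFEDGMVSSLANTYFPQ
MTVLEGMDCFIIHYPIKIYDHKMCRSSYDLYTYVSDDSTESPYLLLTGADVDLKTTRLPDANYSPLTLQGRTPGFENTSV
PWRLELSDLRVWFYADVRLMMVELAFFFEVEPATLRRGIPPAVAGNCLGQDEVWRTFPASDFVKDHMLHFPKEFQGQWKY
APVRYLADVYSEDSSISVETNIPQGGWNDAAFGLPGCSNWYASFKPDAYHEWPMLDKLNLTFETQLKRRKTKEGKINRDG
PRFVFTLTPDYKRTVQMQWNGIIAFQWYNGGKTSPESPVG
>DnaE1_anchor2
GNLVHTHSIVEASLYEQTPDDLHVLKTPSTEKQNTSQGISEAHFFTNITENLAIICSNAGDHPDSHVGPIAAPKALAIMD
MTAWLEGIAVLEKLNTEAVILVIQFSYIQYLLPFAVIETSEQRKDDSEAVRRLAHALCAKGGIDFEDGMVSSLANTYFPQ
MTVLEGMDCFIIHYPIKIYDHKMCRSSYDLYTYVSDDSTESPALLLTGADVDLKTTRAPDANYSPKTLQGRTPGIENTSA
PWRLEKSDLRVWFYADVRLMMVELAFFFEVEPATLRRGIPPAVAGNCLGQDEVWRTFPASDFVKDHMLHFPKEFQGQWKY
APVRYLADVYSEDSSISVETNIPQGGWNDAAFGLPGCSNWYASFKPDAYHEWPMLDKLNLTFETQLKRRKTKEGKINRYG
PRFVFTLTPDYKRTVQMQWNGIYAFQWYNGRKTSPESPVG
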