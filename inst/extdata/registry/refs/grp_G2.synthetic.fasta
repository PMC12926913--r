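>G2_anchor1
GFQKTVLPSPRTTDAPVVSREIGISDRCRLIAKIDHLVDVLIYMKVGGLQEVVKTWNLFCPAPGRCAAKKQRIEYQLRAW
LTQPAKDEDEMESNRDRRQHDGVANICGLSLTPIKEESFKCWTQQETLEFNWMTGGLEGEWFLGSPEGKYDFYDTNMTTS
NGDAVYANEALEVKRLRFGRDNCATGKLEFRRTARRVEHMGVSPLCLMRKIYKQQWGYSEIPRIPLDFAVAVGSSSAHDD
KGDLVCIAGMKYPFAVVLIDLVTTGADIRVTLMVTRKDVDISVDINPDSDLDEQSNPPQLMDSTLQYFNEADKERFKTEG
SLGDIISRKQCLGEKKLFAYANTGLELKGQVAILNGVPSFSVADKFEFGW
>G2_anchor2
GFQKTVLPSPRTTDAPVVSWEIGISDRCRLIAKIDHLVDVLIYMKVGGLQEVVKTWNLFAPAPGRCAAKKQRIFYLLRAW
ATQPAKDEDEMESNRDRRQHDGVANICGLSLTPIKEESFKCWTQQETLEFNWMTGGLEGEWFLGAPEGKYDFYLTNMTTE
NGDAVYANEALEVKRLRFGRDNCATGKHEFRRTARRVEHRGVSPLCLMRKIYKQQWGYAEIPRAPLDFAVAVGSSSAKDD
KFDLVCIAGMKYPFAVVLIDLVTTGDDIRVTLMVTRKDVDMSVDINPDSDLDEQSNPPQLGDSTLDYFNEAFRERFKTEG
SLGDIISRKQCLGEKKLFAYANTGLELKGQVAIANGVPSFSVADKFEFGW
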