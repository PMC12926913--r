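>consensus
RNTARRVEHMGVSDLCLMTKIYKQQWQYSEIARIPLDHASAVGSSSAHDDKADLVCICGMKYPFIVVLIDLVTTGTDSRV
TGMVTRKDVDNMVRITVDSDLDENSVPPQLFDSTLQYTNEPDKEREKTDGSVCDIISRKICLGEKKLFAYTDTGLYLLGS
VAILVGVPSFSVADKFEIGW
>var1
RNTARRVEHMGVSDLCLMTKIYKQQWQYFEIARIPLDHWSAVGSSSAHDEKADLVVICGMKYPFIVVLIDLVTTGTDSRV
TGMVTRTDVDNMVRITVDSDVDENSGPPQLFDSTLQYTNFPDKEREKTDGSVCDICSRKICLGEKKLFAYTDTGLYLLGS
VAILVGVPSFSKADKFEIGW
>var2
RNTARRVEHMGVSDLCLYTKIYKQQWQYSEIARCPLDHASAVGSWSAHDDKADLVCICGMKYPFIVVLIDLVTTITDSRP
TGMVTRKDVDVMVRITVDSDLDENSVEPTLADSTLQYTNEPDKEREKTDGSVCDIISRKICLGEKKLFAYTDTGLFLLGS
VAILVGPPSFSVADKAEIGW
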