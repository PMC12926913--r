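>.ImuA_anchor1
LKSDVINVLVQQSAFVRVVSPQRGPCRFFAGAENAPNSKSGAMPVIFIGCPEVAKHTTYEFPTLSGLKEHAKSSGVPGKH
PGTGIQVNHFAQHYPWYKSADLVLLGIFERGGLTTALNSH
>.ImuA_anchor2
LKDDVINVLVQQSAFVRVVSPQRGPCRFFAGAENAPNSKSGAMPVIFIGCPEEAKHTTYEFPTLSGLTEPAKSSGVPGKH
PGTGIQVNHFAQHYPWYKSADLVLLGIFERGGLTTALNSH
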