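>consensus
LKSDVINVLVQNSAFVRVVSPQKGPCRFFAGAENAPNSKSGAMPVIFIGCPEVAKHTTYEFPTLSGWKEHAKSSGVPGKH
PGTGIQVNHFAQHYKWYKSADLVLLGIFERGGGTTALNSH
>var1
LKSDVINVLVQPSAFVRVVSPQKGPCRFFAGIENAPNSKSGAMPVIHIGCPEVAKHTTYEFPTLSGWKEHNFSTGVPGKL
PGTGEQVNHFAQHYKWYKSADLVLLGIFERPGGTTELNPH
>var2
LKSDVIKVLVQNSAFVIVVSPQKGPCRDFAGAENAPNSKSGAMPVIFIGCPFVAFHTTDEFPTLSGWKEHAKSSSVPGKH
PGTGIQVNHFAQHYKWYKSADLVPLGIPERGGGTTALDSH
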