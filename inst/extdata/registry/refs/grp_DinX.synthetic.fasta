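>DinX_anchor1
VGCLTAFELINITNLPGESVLKITILESPDSNKPGRGEWYMEEENPSLEGEGLDPPDKSDGEGVFARPDCKGVGLREQGD
LLKQTRKNSDYEEGRGTHAPWMKHEEALRWETQEFDATNKPAFTPNVVLGFELDKCIITGPIDFGLVDSSAGDPDSIIVP
FSKVDSRGETENDISMGGRDLPFGGNNAPDIKVYNDMYAIFVETLGVASMSHGTSDLTENLEDAQHPGFEIIDDQIEVFS
DWDRWLNFDEDHFIGRHIDGNRQSSLFLDGAPSDMEYTMIEIWTAKSEERLQMAVINAWRRPRYTDQVAGIVRFSELHAH
QSNPLLLRCE
>DinX_anchor2
VGCLTAFTMINITNLPGESVLKITILESPDSNFPGRGEWYMEEENPSLEGEGLDPPDKSDGEGVFARPDCKGVGVREQGD
LLKQTRKNSDYEEGRGTHAPWMKHELALRWETQEFDATNKPADTPNVVLGFELDKCIITGPIVFGLVDNSAGDPDSIIVT
FSKEDSRGETENDISMGGRDLPFAGNAAPDIKVYNDMYAIFVETLGVASMSHGTSDKIENLEDAQHPGFEIIDDQIEVFS
DWDRWLNYDCDHFIGRHIDGNKQSSLFLDGAPSDMHYTMIEIWDAKSEERLQMAVWNAWRRPRYTDQVGGIVRFSELHAH
QSNGLLLRCE
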