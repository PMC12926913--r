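>consensus
DQKSLAIMPLCVGETSFVQVIVGVPKGHPDVYKNNNHKGTNQWSIRKQFYANSCKTWREDLEKPYMIEWLNQASTADAFQ
ILQGVSCDNDKADEALASDNPMDRTIEIFLDPKEDGNSYKQSAWKMQAIDLGQYLWNKLYDEKGGTRMRR
>var1
DQKSLAIMPICVGETSFVQVIVGVPKGHPEVYKNNNHKATNQWSIRKQFYANSCKTWREDLEKPYMIEWLNQASTADAFQ
ILQGVSVDNDKADEALASDNPMDCTIEIALDPKEDGNSYKQSAWKMQRIELFQYLWNKLYDEKGGTRMRR
>var2
DQKSLAIMPLGVGELSFVQVIVSVPKGHPDVYKNWNHKGTNQWSIRKQFYANSCKTWREDLEKPYMIEWLNVYSTADAFQ
ILQGVSCDNDKADEALASANPMDRTIEPFLDPKEDGNSYKQSADKMQAIDLGRYLWNKLYDEVGGTRMRR
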