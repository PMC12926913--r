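>ImuB1_anchor1
NLVKTAFELINITNFTSENGLSNLILESPDEAKPGRERLYMEEENPSLQGSGLDPPDKSDGEGVFARPDMKGVNLREQPD
LLKQTKKNSNPAEGRGTHLPWMKLEKELREEGQEFKINNVPYFETWVVLLFECNGCSQTLDSDFSRVDLFFLLALEQYVD
AVKADSLGETSNPHSMGGSPLPCGSNGAVLIKTYNDGQAINPNYLDKFINGHNTRLLTENSEDFQHPGSEKILKQIEDFD
TWDRWEAQVSNPFSRRRIDELGQSSLFDRMDHRIVKRLNIFPKNKERLASSNQPGPREKCEHDVVTAKMNRILSIGLMAA
TNNAGPGRTKNQGTDIFAGGLELFHIEMTFDDVLYINIRA
>ImuB1_anchor2
NLVKTAFELINITNYTSENGLSNLILESDDEAKPGRERLYKEEENPSLQGSGLDPPDKSDGEGVFLRPDMVGVNLREQPD
LLKQTKKSSNPAEGRKTHLPWMKLEKELGEEGQEFKINNVPKFETWVVLLFEGNGCSQTKDSKFSRVDLFKLLALEQYVD
AVKADSLGETSNPHSMGGSPLPCGSNGALLIKTYNDGQAINPQYLDKFINGHNTRLLTENSEDFQHPGSEKILKQIEDFD
TWDRWEAQVSNPFSRRRIDELGQSSLFDRMDHRIVKRLNIFPKNKERLASSNMPGPREKCEGDVVTAKMNRILSIGLEAA
TNNAGMGREKNVGTDIFAGGLELFHIEMTHDDVLYINIRA
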