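>PolX1_anchor1
TVDDKSSIYNNQITRKFLGPEDFRTLRSMYYRICIKKTDKGKESPPDAAASTQINVVTALWLYELSISESDQKVLAGRPL
CVGETSFVPVIVGVVKGHPDVYDNNNHKFTNQWSIRKTFTANSCKTWMEDLELLYMIEYLTQAVLAQAFQILQTVSADND
AADEGLPSDKFGDRSIEIELDPKEDGNSYKPSAWKMQAIDLNPYLWSKLYDEKGGTRKRRLLLKDYVVDNGNLVHTHSIV
MASIYEATPNDLHVVKTPQDEKHVAPHTESEVHFFTNITVNLAIECLNVGDHEAVHTGAIRNGKALANMSQGTQLEGIAV
PEKLHICAMI
>PolX1_anchor2
TVDDKSSIYNNQITRPFLGPEDFRTLRSMYYRICIKKTDKGKESPPDAAASTQINVVTALWLYELSISESDQKVLAGRPL
CVGETSFVPVIVGEVKGHPDVYDNNNHKFTNQWSIRKTFTTNSCKTWMEDLELLYMIAYLTLAVLAVAFQILQTVSADND
AADEGLPSDKFGDRIIEIELDSKEDGNSYKPSAWKMQAIDLNPYLWSKLYDEKGGTRGRRLLLKDYVVDNGNLVHTHSIV
MASIYEATPNDLHVVKTPQDEKHVAPHTESEVHFFTNITVNLAIECLNVGDHEAVHTVAIRNGKALAFNSQGTQLEGIAV
PEKLHICAMI
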