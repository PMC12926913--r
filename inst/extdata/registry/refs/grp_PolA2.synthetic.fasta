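>PolA2_anchor1
SKAKSNMLPSIGIVGLKEGLATDKNHTQIFRPGTSEAPSLGIVEKSDQVWHLQDFDYVDDMESERDRRPHDTEGNICKLV
LTPLYEEEFKKWPHGETLTFNWMTGYIRTELFLGSPEPAQSSLFTAMTTINGDVVYHNESFEVKRLRFKNYPVTIQVLAS
ITASWSTPDFVQFLRNFCRPMNGLNGYCKNGTKAQFHRTVEGKSSAEKRYQYLKVIITKCLGPDFRETADSCGVEYFDNM
KADDEHSRSVNKDVIFSFKDVLEATLKVKLDDHEWDILTFEMGNSQNQTKVKNMSQNQMTAIVVVEWKDVMDLIFAYPTL
APEHGLHIIEYLTNNGDFST
>PolA2_anchor2
SKAKSNMLPSEGIVGLKEGKATDKNHTQIFRPGTIEAPSLGIVEVSDQVWHLQDFDYVDDMESERDRRPHDTEGNICKLV
LTPLYEEEFKKWPHGETLTFNWMTGYIRTELFLGSYEPAQSSLFTAMTTINGDVVYHLERFRVKRLRFKNYPVTIQVLAS
MTASWSTPDFVQFLRNFCRPMNGLNGYCKNGTKAQFHRTVEGKSSPIKRYRELKVIITKCLGPDFRETADLCGVEYFENM
KADDEHSRSVNKDVIFSFKDVLEATLKVKLDDHEWDILTFEMGNSQNQTKVKNMSQNQMTAIVVVEWKDVMDLIFAYPTL
ATEHGLHIIEYLTNNEDFST
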