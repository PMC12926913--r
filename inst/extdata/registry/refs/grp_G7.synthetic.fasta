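>G7_anchor1
MEANRDRRQHDNEANIVKLTLTNITETSAKKWRQQETLEIDWMTGGLEGEWLLGSPEGKYDFYETAMTTGNGDARYANEQ
FEVKRLRFGIAQHDPYGVYGRTTAHPVEGMGESDLCLVTRIYKQSWQYEEIARIPLLLASAVGSSSGHVDSGDLVCICGM
KYFFIVVRIDLLTTGTVSRVTEMVTRKEVDNMVRPTNDIDLLENSVPPQLFDLTLQYTNAPDKEREGTDGSVCDIKSRKI
SLDEKKLFYYTDEGLYKLYSVMILVLYPSFSVAGKFEIGW
>G7_anchor2
KEANRDRRQHDNEANIVKNTLTNITETSAKKWRQQETLEIDWMTGGLEGEWLLGSPEGKYDFYETARTTGNEDARYANSQ
GHVKRLRFGIAQHDPYGVYGRTTVHPVTGMGESDLCLVTRIYKQSWQYEEIARIPLLLASQVGSSSGHVDSGDLVCICVM
KYFFIVVRIDLLTTGTVTRVTTMVTRKEVDNMVRPTNDIDLLENSVPPQLFDLTLQYTNTPDKEREGTDESVCDIKSRKI
SLREKKLFYYTDEGLYKLYSVMILVLYPSFSVAGKFEIGW
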