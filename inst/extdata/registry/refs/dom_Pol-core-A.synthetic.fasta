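>consensus
ITASSSLPDFVNKRRNCLRPMNTLNGYCSNGTKAQVTSTVEAKSSAEKRYQYLARIITKCLGPDFYQTADSCGVSYFDNL
VADDEHSRSNAKDVILSFKDVNEATRKHKLDTIEWRIQTFEMRNSQNQTKLKNFEQLTMEAIVVYEWNDAMDDIFSYPGV
PPEVGLQIITYLTNNGDFST
>var1
ITASSSLPDFVNKREDCLRPMNTLNGLCSNGTKAQVTSTVEAKSSAEKRYQYLARIITKCLGPDFYGTADSCGTSYVDNL
VADDEHSRSNAKDVIASFKDVNEATRKHKLDTIESRIQTFEMRNSQNQTKLKNFAQLTMEAIVVYEWNDAMDDIFSYAGV
PPGVGLQIITYLTNNGDFST
>var2
ITASSSLPDFVNKRRNCLRPMNTLNGYQSNGTKAQVLSTVEAKSSAEKRRQYLCRIITKCLEPDFYQTADSCGVSYFDNL
VADDEGSRSNAKDVILSFKDVNEATRKHKLDTIEWRIQTFEMRRSQNWTKLKIFEQLTMEAIVVYEWNDAMDDIFSYPGV
PPEVGLQIITYSTNNGDFST
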