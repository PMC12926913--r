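>PolA3_anchor1
LESNRDRRQHDSVHNICTLSKTPIGEPLLKQWGGQETLESDSMLSILEVESFFGSPEWKYDQYETSMTDSNGDAVYANED
QEWKRLRFGICAVNSVIYLSITASSSGPTFVLKRRNCLRPMNTLNGYSSNGLKYQVISTVEAKSSARKRLQYSARIIAKC
LQLDFYQTADHCGVSYLDNLVPKDFHLRSNWKDVILSFKDVNEATRDHKCDTIEWRIQDFTMRMSQNQTKLPAQEQLTMV
AIKVYEADDRFDNVFSYPGLEPNVTDQIITYLATNGDTST
>PolA3_anchor2
LELNRDRRMHDSAVNICTLSKTPIGEPLLKQWGGQETLESDSMLSILEVESFSGSPEWKIDQDETSMTDSNGDAVYANED
QEWKRLRFGICAVNSVIYLSITASSSGPTFVLKRRNCLRPMNTPNGYSSNGLKYQVISTVPAKSSARKELQYSARIIAKC
LQLDFYQTADHCGVSYFDNLVPKDFGLRSNWKDVILSFKDLNEATRDHKCDTTEWRIQDFTMRMSQNQTFLPAQEQLNMV
AIKVYEVQNRFDNVFSYPGHEPNVTDQIITFLATIGDTST
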