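>PolA1_anchor1
WPQVTESDGVRGAQNILCTTADPDKTRENTKSNFNSLPLEDEAPMANPYIVPLRWALDIEAKVVRKDSGCGDALQVTFDD
SMNILVIYLFDQMPLAKTELKGSHNDRSQHDPVANICKLFNTPIKEESFKKWTQRAKVEFDAMTGGLEVEWFVQSPEGKY
DKYEPAMTTSNGDAVYHNLSFEVKRLRFGIAGITMDSIWLKTESDSLPDFGELRENCVGLMNTLNGYLSNGTKAQVTSFV
NAKSSAEKRYQYCGRIITKCLGPEFYHTADIKGVSGFDQLVADDLYSRSNAKSVSLEFKDVNEMTRTHKLDTIEWRIQAF
VMRLSQNQTDLKNFEQLHMEAIVVPVWNDQMDDNFSYPGVPPGVGAQIITYLMPNGDFSV
>PolA1_anchor2
WPQVTESDGVRGAQNILCTTADPDKTRLNTKSNFNSLPLEDEAPMANPYILPLRWALDIEAKVVRKDSGCGDALQVTFDD
SMNILVIYLFDQMPDAKTELKGSHNDRSQHDPVANICKLFNTPIKEESFKKWTQRAKVEFDAMTGGLEVEWKVQSPEGQY
DKYEPAMTTSNGDAVYHNLSFEVKRLRFGIAGITMDSIWLITESDSLPDFGELRENCVGLMNTLNGYLSNGTSAQVTSFV
NAKSSAEKRYQYCGRIITKCLGPEFYHTADIKGVSGFDQLVAFDLYSRSNAKWVSLEFKDVNEMTSTHKTDTIEGRIQAF
VMRLSQNITDLKNFEQLHMEAIVVPVWNDQGDDNFSYPGVPPGVGAQIITYLMPNGDFSV
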