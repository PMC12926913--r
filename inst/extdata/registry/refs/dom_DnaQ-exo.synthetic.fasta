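>consensus
MESNRDRRQHDTVANICKLSLTPIKEESFKKWTQQETLEFDWMTGGLEVEWFLGSPEGKYDFYETAMTTSNGDAVYANES
FEVKRLRFGI
>var1
MERNRDDRVIDTVANITKLSLTPIKEESFNKWTQQETLEFDWMTGGLQVEWFLGSREGKYDFYETAMTKSNGFAVYANES
FEVKRLRFTI
>var2
MESNRDRRQHDTVDNICKQAQTPIKEESFKKWTQQETLEFDWMIGGLEVEWFLGSREGKYDRNETAMDTSNGDAVYANSS
FEVKRLRFGI
>deddy
MESERDRRQVDTVANICKLSLTPIKEESFKKWTQQETLEFDWMTGGLEVEWFLGSPEGKYDFYETAMTTSNGDAVYANES
FEVKRLRFGY
>distant
MEPVSDRRQSVTLAEISQELSCKIVEGSKCKRDCTLADFFDEMDYGLNVEEKLGSLEPKLDVYMTLMITSQNPAGYASNS
FGRHRLGFFI
>distant_var
MEPVLDRRQSATIAEISQELSCKIVEGSKCKRDCTSADFFDEMDYGLNVEEKLGSLEPYLDVYMVLTILSQNPAGYASNS
FERHRLGFFI
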