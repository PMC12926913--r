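>vDnaQ1
MESNRDRRQHDTVANICVLSLTPIKEESFKKWTQQETLEFDWMTGGLEVEWFLGSPEGKYDFYETAMTTSNGDAVYANES
FQVKRLRFGI
>vDnaQ2
MESNRDRRGHDTVANICVLSLTPIKEESFKKWTQQETLEFDWMWGGLEVEWFSGSPKGKYDFYETAMTTSNKDAVYANES
FQVKRLRFGI
>vDnaQ3
MLSNRDRRQHDTVANICVLSLTPIKEESFKKWTQQETLEFDWMTGGLEVEWFLGSPVGKYDFYEDAETTSNGDAVYANES
FQVKRLRFGI
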