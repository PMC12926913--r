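>.DnaQ-solo_anchor1
MESNRDRRQHDTVANICVLSLTPIKEESFKKWTQQETLEFDWMTGGLEVEWFLGSPEGKYDFYETAMTTSNGDAVYANES
FQVKRLRFGI
>.DnaQ-solo_anchor2
MHSNRDRAQHDTVANICVLSLTPIKEESFKKWTQQETLEFDWMTGGLIVEWFLGSPEGKYDFYETIMTTSCGDAVYANEL
FQVKRLRFGI
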