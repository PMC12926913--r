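>G6_anchor1
MQSNRDSRQHDFAAAICVLQLTSIKEESFISWTQQETLEFDWDTHGLEVSWFLNNPEGKYDFYFTAMTTSKWDAVYANES
FEVKRSRFGINESTNSPATQRNTAGPVSHMGQVDLYGAEKIYKAQWQIVEIARGPLIHQSAVGSSSAHDKLNDLLCICGM
KYPFIVTLQDGVTTGTDSRVTGMVTPKDVDNMVGIVVDSDLDENLPPLQLFDKTLILTNEADSEREKADGSVCDIISGFQ
CLGKKKLDAYTYTGLYLLGSVAILAGKPGFSMADKFNIGE
>G6_anchor2
MQSNFDSRQHDFAAAICVLQLTSIKEESFISWTQQETLEFDWDTHGLEVPWFLNSPEGKYDFYFTAMTTSKWDAVYANES
FEVKRSRFGINESTNSPATQRSTEGPVSHMGQVDLLGAEATYKAQWQIVEIARGPLIHQSAVGSSSAIDKLNDLLCICGM
KYPFIVTLGDGVTTGTDSRVTGMVTPKDVDNMVGIVVDSDLDENLKPLQPFDATLILTNEADSEREKADGSVCDIISGFQ
CLGKKKLDAYTYTGLYLLSSVAILAGKPGFSMADKFNSGE
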