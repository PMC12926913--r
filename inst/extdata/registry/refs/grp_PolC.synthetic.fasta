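>PolC_anchor1
GSLVHTHSIVKASLYEQTPDDLHVVLTPSDECAVAPHGESEVHFRTLITENLAIECVIAGDHFSSHVGAIAAPKKLANKG
ATAWLEGIISPKKLHLCMPAAVPSPVSGIEMRSNGDRRKHDTAANICTLSLTPIKEESFKKWKQQETSGFDWMEGGLEVE
WFLGSEDGKYDFMEVAMTTAFTDAVYANESFVVKRLRTGICIGGSGGAASALDIAVIETTLYDSKDYWKWRRLAFLACNK
FGTWIEDYRVSSLYNSYQPDMTVGEGAPCFSIHYPMKSCDPKMCRPSYDAYPYVPPDSTESPYLVLTGNDVDHKTTRLPE
ANVRPGTILGRTPGFENGSVIWRAIFWDIRAWFLADVLFLMGELAFKILVGVARLTPKVDPAIAINMRGQ
>PolC_anchor2
GSLVHTHSLVKASLYEQTPDDLHVVLTPSDECAVAPHYESEVHFRTLITENLAITCVIAGDHFVSHVGAIAAPKKLANKG
ATAWLEGIISPKKLHLCKNAAVPSPVSGIEMRSNGDDRKHDTAANICDLSLTPIKEESFKKWKQQETMGFDWMELGLEVE
WFLGSEDGKYDFMEVAMTTAFTDAVYANESFVVKRLRTGICIGGSGGAASALDIAVIATTLYDSKDYWKWRRLAFLACNK
FGTWIEDYRVSSLYNSYQPSMTAGEGAPCESIHYPMKSCDPKMCRPRYDAYPGVPPDSTESPYLVLTGNDFDHKTTRLPE
ANVRPGTILGRTPGFENGSVIWRAIFWDIRAWFLADVLGLMGELAFKILVGVARLTPKVDPLIAINMRGQ
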