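>DnaE2B_anchor1
GNLVHAHLIVMWSLYENTADDLHLVYPPSDLKAVAPHCESNVHFFIGIMENLDINCLPRGDHFSSHGGAIAFPKSLANVD
MTGRLEGKKVPEKFHLCAAIRQGDSLYEEFLLMFTFIETTLYASKDYWVWRRLAFALCNAFGIAILDYVVPGLYTHGWIQ
MTVLEEADNQKIIYPGGSCDHKCCRSSYDSYTYLSPDGTESPYLRVTGNDVDLKTTRTPEASVQLLSILILTPGMPVGGV
PLRAEVGVIRNWGLADVTLLMGELAFFVEVEEATLCRKVPPAVAGGDRCQ
>DnaE2B_anchor2
GNLVHAHLIVMWSLYENVGDDLHLVYPPSQLKAVAPPCESNVHFFIGIMENLDINCLKRGDHFHSHGGAIAFPKSLAYVD
MTGRLEGKKVPEKFLLEDAIRQGDSLFEEFLLMFTFIEITLYASKDYWVWRRPAFALCNAFGIAILDYVVPGLYTHGWIQ
MTVLEEADNQTIIYPGGQCDLKCCYSSYDSYTYLSPDGYESPYLRVTGNDVDLKTTKTPEASVQLLSILILTPGMPVGGV
PLRAEVGVIRNWGLADVTLLSGELAFAVEVEEATLCRKVPPAVAGGDRCQ
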