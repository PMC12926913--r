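>consensus
SPSDMEDTMIAAWTAKSEESLQMAMENAVRRPSYTDQVQGIVRFSELHAHGSNPLLLRCE
>var1
SPDDMEDTMIAAWTAKSEESLQMAMENAVARPSYTDQFQGIVRFSELHAHGSNPLLLRCE
>var2
SPSDMELTMIAAWTAKSEESLQMAEETAVRRPSYTDQVQGIVRFSELHAHGSNPLLERCE
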