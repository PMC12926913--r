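>consensus
TYPKARVFPAIKLQNVLDCLLYLVVAKGFVAGVGESFILSRCYEARLAGPMLNSHVGIDT
>var1
TYPKARVFPAIKLQNVLDCLLYNVVAKGFVAGVGESFILSNCYEARLAGPMLNSHVGPDT
>var2
TYPKARTFPDIKLQNVLQGLLYLVVAKGFMAGVGLSFILSRCYEARLAGPMLNSHVGIDT
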