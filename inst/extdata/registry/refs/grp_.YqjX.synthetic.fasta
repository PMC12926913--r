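>.YqjX_anchor1
YTQSRVRKGVGKVGTYLQDKDFHVAGAGGGLDAFNYDLYSTYPKARVFPAIKLQNVLDCLLYLVRAKGFVAGVGESFILS
RCYEADLAGPMLNSHVGIDT
>.YqjX_anchor2
YTQSRVRKGVGKVGTYLQDKDFHVAGAGGGLDAFNYDLYSTYPKARVFPVIKFQNVLDCLLYSVRAKGFVAGVGESFILS
RCYEAGLAGPMLNSHVGIDT
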