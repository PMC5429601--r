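name	gain	loss
methyl	CH2	
acetyl	C2H2O	
oxidation	O	
deamidation	O	HN
disulfide		H2
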