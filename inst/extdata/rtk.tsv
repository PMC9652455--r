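pathway	protein	weight
RTK	EGFR-pY1068	+1
RTK	EGFR-pY1173	+1
RTK	HER2-pY1248	+1
RTK	HER3-pY1289	+1
RTK	SHC-pY317	+1
RTK	SRC-pY416	+1
RTK	SRC-pY527	+1
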