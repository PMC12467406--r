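population	bF	F1	Sp_printed
BMXS	-0.0204	0.0531	0.021
MGFD	-0.0075	0.0176	0.0076
SXFP	-0.0133	0.0297	0.013
GLGS	-0.012	0.0362	0.012
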