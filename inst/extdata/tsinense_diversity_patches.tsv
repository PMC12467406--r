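population	patch	num_indv	ho	he	fis
BMXS	YA	9.470	0.020	0.083	0.171
BMXS	YB	8.946	0.019	0.083	0.172
BMXS	YC	8.870	0.018	0.084	0.178
GLGS	GA	7.796	0.017	0.111	0.252
GLGS	GB	7.602	0.016	0.106	0.241
GLGS	GC	7.328	0.024	0.112	0.237
MGFD	MA	10.644	0.022	0.134	0.314
MGFD	MB	8.861	0.022	0.125	0.285
MGFD	MC	10.674	0.020	0.132	0.314
SXFP	FA	4.356	0.022	0.075	0.136
SXFP	FB	4.866	0.020	0.078	0.149
SXFP	FC	5.269	0.025	0.084	0.155
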