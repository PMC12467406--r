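population	patch	seed_max	seed_mean	pollen_max	pollen_mean	gene_effective_printed
BMXS	YA	398.57	168.87	386.20	201.89	221.13
BMXS	YB	463.52	200.89	133.01	55.05	204.63
BMXS	YC	165.44	112.10	167.54	74.11	123.74
BMXS	means	NA	160.62	NA	110.35	183.17
MGFD	MA	61.76	28.97	49.16	27.00	34.70
MGFD	MC	61.00	35.91	78.94	34.17	43.28
MGFD	means	NA	32.44	NA	30.59	38.99
SXFP	FB	187.69	117.78	156.67	101.90	138.07
SXFP	FC	82.06	39.68	74.54	39.37	48.47
SXFP	means	NA	78.73	NA	70.64	93.27
GLGS	GA	63.66	28.54	39.53	25.61	33.80
GLGS	GB	75.62	22.27	68.78	31.87	31.68
GLGS	GC	67.09	37.99	84.06	42.56	48.47
GLGS	means	NA	29.60	NA	33.35	37.98
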