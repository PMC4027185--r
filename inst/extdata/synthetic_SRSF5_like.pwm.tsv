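# name=synthetic_SRSF5_like alphabet=ACGT
# synthetic stand-in emulating the format and shape of published SR-protein matrices
2.51	-3.12	2.34	1.79
-0.27	0.78	1.39	1.23
-0.29	0.25	2.63	-0.56
3.19	-1.55	1.94	-0.42
0.79	0.48	0.21	5.53
0.75	2.81	-0.47	1.27
1.62	-0.68	-0.96	-0.54
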