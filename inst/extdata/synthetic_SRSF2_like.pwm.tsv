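# name=synthetic_SRSF2_like alphabet=ACGT
# synthetic stand-in emulating the format and shape of published SR-protein matrices
-0.93	-0.77	0.22	2.67
0.9	0.13	-1.91	2.59
3.29	-0.21	0.7	0.85
2.18	0.63	1.1	0.59
1.05	2.75	-1.15	3.13
0.62	1.94	1.49	-0.72
-1.95	1.95	-0.22	2.91
-0	4.28	-0.24	-2.21
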