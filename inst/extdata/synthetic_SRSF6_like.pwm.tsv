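# name=synthetic_SRSF6_like alphabet=ACGT
# synthetic stand-in emulating the format and shape of published SR-protein matrices
1.57	0.94	4.47	0.09
-0.99	-0.07	0.29	1.67
-0.44	1.3	-1.64	3.25
-0.57	5.02	1.84	1.16
0.72	2	-0.92	1.16
-0.72	-0.92	2.83	-1.2
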