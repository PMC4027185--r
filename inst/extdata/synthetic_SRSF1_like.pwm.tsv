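# name=synthetic_SRSF1_like alphabet=ACGT
# synthetic stand-in emulating the format and shape of published SR-protein matrices
3.23	-2.52	1.72	0.6
4.11	-1.29	-0.83	-0.02
1.56	1.97	-0.97	-2.27
-0.4	-0.92	3.87	-1.44
1.5	0.08	3.02	-0.04
-1.04	0.47	-0.45	3.48
1.83	2.05	-1	1.88
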