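# synthetic_fas_hex3_ess: synthetic stand-in emulating a scored silencer hexamer set (log2 pseudoexon/exon odds)
AAAATT	0.301
AACAAT	1.317
AACGTT	1.44
AAGGTC	2.364
AATGAT	1.566
AATTGG	2.126
AATTTT	2.157
ACAAGG	2.511
ACTAGA	0.803
AGAGTG	2.499
AGCAGT	2.409
AGGTTA	2.548
AGTTCT	2.502
ATACCA	0.781
ATACTT	2.446
ATCAAT	2.455
ATCTGG	0.527
ATGCGT	1.857
ATGGTC	1.1
ATGTTC	1.17
ATTAGT	1.245
ATTTTC	1.867
CAAAAA	1.497
CACCTA	1.944
CATTTT	2.516
CCCAGG	2.492
CCCATG	1.864
CCCTAT	2.473
CCGGAT	0.9
CCGTTC	1.679
CGTTGG	2.221
CTATGT	2.017
CTCATA	2.131
CTGGTG	1.84
CTGTGC	2.373
CTTATT	1.236
CTTGTT	2.345
CTTTTT	2.116
GAATCA	1.774
GACTCT	0.973
GAGAAG	2.531
GAGACC	1.966
GAGATC	2.499
GATTAA	2.167
GCCGTT	2.208
GCTGTG	2.029
GCTGTT	2.539
GGACTC	0.705
GGATAC	2.475
GGCTAT	2.077
GGTGAT	1.281
GGTGTG	2.111
GGTGTT	1.184
GTAGTC	1.731
GTCCTT	1.802
GTCGGC	1.03
GTCTTG	0.612
GTGTGT	2.438
GTTATC	1.968
GTTCAG	2.048
GTTCAT	1.911
GTTGGG	1.148
GTTTGC	2.148
TAAAGG	0.997
TAAATC	1.25
TATACT	0.519
TATGAA	2.426
TATGAT	1.786
TCACCC	2.012
TCAGAC	0.48
TCATTG	1.37
TCCTCT	2.579
TCTTTA	0.339
TCTTTG	2.423
TGACGT	0.903
TGCACT	1.727
TGCTGG	2.538
TGCTTG	2.33
TGGATG	0.905
TGGATT	1.179
TGGCTG	2.246
TGGTGA	0.871
TGGTGC	2.109
TGGTGG	2.346
TGGTTC	2.269
TGTGTT	0.841
TGTTGG	1.447
TTACGT	2.232
TTATAT	1.978
TTATGG	1.195
TTATTC	2.532
TTATTG	2.417
TTATTT	1.59
TTCTAG	2.476
TTCTGA	0.625
TTGAGA	2.134
TTGGCC	1.251
TTGGGA	2.314
TTTTAT	1.597
TTTTCG	2.321
TTTTCT	2.401
TTTTGG	2.213
TTTTTC	2.004
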