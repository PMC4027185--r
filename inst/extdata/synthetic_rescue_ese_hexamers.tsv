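# synthetic_rescue_ese_hexamers: synthetic stand-in emulating a 238-member enhancer hexamer list
AAAAGG
AAACAA
AAACGA
AAAGAA
AAAGAC
AAAGAG
AAAGCA
AAAGGC
AAAGGG
AAATGG
AACAAA
AACTGC
AAGACA
AAGACG
AAGACT
AAGCGA
AAGGAG
AAGGAT
AAGGCC
AAGGGG
AAGGTA
AAGTAA
AATAAG
AATAGT
AATATA
AATGGA
AATGTG
ACAATG
ACAGCG
ACAGGG
ACGAAA
ACGAAT
ACGCCT
ACGCGA
ACGGAA
ACGGAT
ACGGGT
ACGGTC
AGAAAC
AGAAAG
AGAAGA
AGACGG
AGAGAT
AGAGCA
AGAGGA
AGAGGC
AGAGGG
AGAGGT
AGAGTT
AGATAT
AGCAAA
AGCAGA
AGCTAG
AGCTGG
AGGAAA
AGGAAT
AGGACG
AGGAGG
AGGCGG
AGGCTT
AGGGAC
AGGGCA
AGGGCG
AGGGTA
AGGGTG
AGGGTT
AGGTAC
AGTAGG
AGTAGT
AGTCCA
AGTGCA
AGTTGG
ATAAAG
ATACCG
ATAGAT
ATAGCT
ATAGTT
ATCAAG
ATCATA
ATGACT
ATGAGA
ATGGTA
ATGTGG
CAAACG
CAAGGG
CACGAG
CACGGA
CAGAAG
CAGAGC
CAGAGT
CAGATG
CAGCGA
CAGGCG
CAGGGA
CAGTAA
CATAAG
CATCTG
CATGAA
CCAGCG
CCTATC
CGAAAA
CGAAGA
CGAGAG
CGCACT
CGGAAG
CGGGAA
CGGGGA
CGGTTA
CTAAAA
CTAAAG
CTACAT
CTAGCA
GAAAAG
GAAAGG
GAAAGT
GAAATA
GAACGC
GAAGAA
GAAGAG
GAAGGA
GAAGTA
GAATAT
GAATGG
GACAAG
GACCCG
GACGAA
GACGCG
GAGAGG
GAGAGT
GAGATG
GAGCGA
GAGGAC
GAGGGA
GAGGGG
GAGGTG
GAGTAG
GAGTGG
GATACA
GATAGA
GATAGC
GATAGG
GATTTG
GCAAAG
GCAATA
GCAGGA
GCCAGA
GCGAAG
GCGAAT
GCGAGA
GCGAGC
GCGAGT
GCGATG
GCGGTG
GCTAGT
GGAACT
GGAAGA
GGAAGC
GGAAGG
GGACGG
GGAGAA
GGAGAG
GGAGCA
GGAGCT
GGAGGG
GGAGGT
GGAGTA
GGAGTG
GGCAGT
GGCGAC
GGCGGC
GGGAAA
GGGAAG
GGGAGA
GGGAGG
GGGCGT
GGGCTA
GGGGAC
GGGGCA
GGGGCC
GGGGGT
GGGGTT
GGGTAG
GGGTGG
GGGTTA
GGTAAT
GGTACC
GGTAGG
GGTGGC
GGTGGT
GTAAAG
GTAAGA
GTACGG
GTAGAA
GTAGGG
GTCGAG
GTGAAG
GTGACT
GTGGGC
GTGGTG
GTGTGG
GTTAAA
GTTACA
TAAAAT
TAAACA
TAACAA
TAAGAA
TACAGA
TAGAAT
TAGACC
TAGGAT
TAGGCC
TAGGGT
TATAAA
TATTGT
TCAAAT
TCATAA
TCCGTA
TCTCCA
TCTGGG
TGAAGA
TGAAGT
TGAATG
TGGACC
TGGCTA
TGGGAG
TGGGGT
TGTAGC
TGTCAG
TGTCGG
TGTGGG
TTAAGA
TTAGAG
TTCGTG
TTCTTA
TTGAAG
TTGATC
TTGTAA
TTTCCA
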