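gene,forward,reverse,efficiency,r2,single_peak,accession
Myh1,GGCCTACAAGAGACAAGCTGA,ACTTTCCTGCACTTGGATCA,102.3,0.99,TRUE,NM_030679.2
Myh2,TCTAAGGCCAAGGGAAACCTC,TACCAGCGCTTCCTTCTCATC,107.3,0.99,TRUE,NM_001039545.2
Myh3,TCGCTACAACAGATGCGGAC,CCTGGGGTCTTGGTTTCGTT,92.4,0.99,TRUE,NM_001099635.1
Myh4,CACCTGGACGATGCTCTCAGA,GCTCTTGCTCGGCCACTCT,102.4,0.99,TRUE,NM_010855.3
Myh6,CCAACACCAACCTGTCCAAGT,AGAGGTTATTCCTCGTCGTGCAT,101.3,0.99,TRUE,NM_001164171.1
Myh7,TACTTGCTACCCTCAGGTGGCT,TGTCATCGGGCACAAAAACATC,90.2,0.99,TRUE,NM_080728.3
Myh8,ACGCTAGTGCTGAAGCAGATGG,ACCGTACGAAGTGAGGGTGT,103.7,0.99,TRUE,NM_177369.3
Myh13,CGGCAAGAAGCAGATCCAGA,TCCTCGGCCTGGTAAGTCA,97.4,0.99,TRUE,NM_001081250.2
Myh7b/14,AGACCAGAAGGTGCTGACAGT,CCGGGAGCCATTTGTATGGG,106.6,0.99,TRUE,NM_001085378.2
Csnk2a2,CACCAACAATGAGAGGGTGG,GGTGTCTTTGACACAGGGTCC,97.9,0.99,TRUE,NM_009974.3
Myf5,TGACGGCATGCCTGAATGTA,GCTCGGATGGCTCTGTAGAC,96.0,0.99,TRUE,NM_008656.5
Myod1,TGCTCTGATGGCATGATGGATT,AGATGCGCTCCACTATGCTG,98.1,0.99,TRUE,NM_010266.2
Myog,ATCCAGTACATTGAGCGCCT,CAAATGATCTCCTGGGTTGGG,100.2,0.99,TRUE,NM_031189.2
Egr3,CCGGTGACCATGAGCAGTTT,TTGGGCTTCTCGTTGGTCAG,106.5,0.99,TRUE,NM_018781.4
Gdnf,TGACCAGTGACTCCAATATG,GTTTATCTGGTGACCTTTTCAG,111.7,0.99,TRUE,NM_010275.3
Prph,AGCTACTGGAAGGGGAGGAG,TCCAGGTCACTGTGCTGTTC,92.0,0.99,TRUE,NM_013639.2
Sstr2,GAGAACACAGGGAAGCGAGT,GCTGCTTTCCACTCCGTCTA,110.5,0.99,TRUE,NM_001042606.3
Etv4,CGAGTGCCCTACACCTTCTG,GGGGACTTGATGGCGATTTG,92.9,0.99,TRUE,NM_001316365.1
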