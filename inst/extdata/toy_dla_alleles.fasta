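>DLA-DQA1*00101
GGTTAAGGACGAATTTCCCCGACC
>DLA-DQA1*00201
CCTCTAAGGGGTAGCGAGTGCGAG
>DLA-DQA1*00301
CCCCTCCCAGACAATACAAGCCCT
>DLA-DQA1*00401
GTATTCGGCTGCCTCGTACTACAG
>DLA-DQA1*005011
GCAACCATGTATCCATAGCGGGAT
>DLA-DQA1*00601
CCCCGGTTGGGAGGTGTTGAAGTC
>DLA-DQA1*00901
CGGAGGATTGGACCCGCATGCTGC
>DLA-DQB1*00401
GCTTCTCTTTAGATGCTCGCCGTA
>DLA-DQB1*00501
CACTAGCGTACGGATCCCGGGGTA
>DLA-DQB1*00701
GTGCATTAGCCCGGTACCTGATAC
>DLA-DQB1*008011
CCAGGGAAAGATTTGTTCCCGTTC
>DLA-DQB1*01302
CCTACGTGGGATTCAGTTTGCGTC
>DLA-DQB1*01303
GAATAACTGACTTTTAAGCCTTAC
>DLA-DQB1*02301
TCTTGCTTCTGCTAGTTCGCGGCT
>DLA-DQB1*02901
GAGGTCCCGCATAAGTCCCTCCGA
>DLA-DRB1*00601
TATCGGTGGTCCCGGGCGTGCTTT
>DLA-DRB1*00801
GCGCTGTTGTTTATAAAGAAAGTG
>DLA-DRB1*00901
AATACCCCCCGTTCTATTACAATG
>DLA-DRB1*01101
GACTGATCTGTTCACCCACGCAGA
>DLA-DRB1*01501
ATATACAGTGAGTTGCAACTCCCA
>DLA-DRB1*02001
AGGAGGCCCCGCGCTCAAGTAAGA
>DLA-DRB1*02301
GTGTCCGCTAGGCACTGTTTGATA
>DLA-DRB1*04801
GGCGGACTTTCGGGAATGCCTCTG
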