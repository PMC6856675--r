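"day","systolic_mmHg"
1,94.11287534144
2,90.091619771526
3,94.6608138054406
4,97.255730672026
5,98.3556621122801
6,98.610197880297
7,105.248851706603
8,102.216022884761
9,110.340985427345
10,105.883286274271
11,111.771751819813
12,116.50279332096
13,107.261989325234
14,112.377919413834
15,114.600035990819
16,115.357976182478
17,111.143575714368
18,102.663305449578
19,102.03214843408
20,112.114065964033
21,106.108369897253
22,100.628691798858
23,104.46664262886
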