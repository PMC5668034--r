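age,q
0,5e-04
1,5e-04
2,5e-04
3,5e-04
4,5e-04
5,5e-04
6,5e-04
7,5e-04
8,5e-04
9,5e-04
10,5e-04
11,5e-04
12,5e-04
13,5e-04
14,5e-04
15,5e-04
16,5e-04
17,5e-04
18,5e-04
19,5e-04
20,5e-04
21,5e-04
22,5e-04
23,5e-04
24,5e-04
25,5e-04
26,5e-04
27,5e-04
28,5e-04
29,5e-04
30,5e-04
31,5e-04
32,5e-04
33,5e-04
34,5e-04
35,5e-04
36,5e-04
37,0.000525560259533572
38,0.000573127527002919
39,0.000625
40,0.000681567332915786
41,0.000743254446876701
42,0.000810524721656881
43,0.000883883476483185
44,0.000963881765879963
45,0.00105112051906714
46,0.00114625505400584
47,0.00125
48,0.00136313466583157
49,0.0014865088937534
50,0.00162104944331376
51,0.00176776695296637
52,0.00192776353175993
53,0.00210224103813429
54,0.00229251010801168
55,0.0025
56,0.00272626933166314
57,0.0029730177875068
58,0.00324209888662752
59,0.00353553390593274
60,0.00385552706351985
61,0.00420448207626857
62,0.00458502021602336
63,0.005
64,0.00545253866332629
65,0.0059460355750136
66,0.00648419777325505
67,0.00707106781186547
68,0.0077110541270397
69,0.00840896415253715
70,0.00917004043204671
71,0.01
72,0.0109050773266526
73,0.0118920711500272
74,0.0129683955465101
75,0.014142135623731
76,0.0154221082540794
77,0.0168179283050743
78,0.0183400808640934
79,0.02
80,0.0218101546533052
81,0.0237841423000544
82,0.0259367910930202
83,0.0282842712474619
84,0.0308442165081588
85,0.0336358566101486
86,0.0366801617281869
87,0.04
88,0.0436203093066103
89,0.0475682846001088
90,0.0518735821860404
91,0.0565685424949238
92,0.0616884330163176
93,0.0672717132202972
94,0.0733603234563737
95,0.08
96,0.0872406186132206
97,0.0951365692002177
98,0.103747164372081
99,0.113137084989848
100,0.123376866032635
101,0.134543426440594
102,0.146720646912747
103,0.16
104,0.174481237226441
105,0.190273138400435
106,0.207494328744161
107,0.226274169979695
108,0.246753732065271
109,0.269086852881189
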