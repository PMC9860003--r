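"energy_keV","mu_per_cm"
1,59237.271029
2,7405.008196
3,2194.356054
4,925.972478
5,474.289838
6,274.638156
7,173.094156
8,116.087461
9,81.646711
10,59.624438
11,44.891686
12,34.665339
13,27.345967
14,21.969751
15,17.93227
16,14.841377
17,12.435079
18,10.533796
19,9.011638
20,7.778572
21,6.769051
22,5.934584
23,5.238774
24,4.653942
25,4.158782
26,3.736715
27,3.37471
28,3.062426
29,2.791588
30,2.55552
31,2.348797
32,2.166978
33,2.006406
34,1.86405
35,1.737382
36,1.624286
37,1.522979
38,1.431951
39,1.349919
40,1.275788
41,1.208619
42,1.147604
43,1.092045
44,1.041336
45,0.994952
46,0.952434
47,0.913379
48,0.877436
49,0.844295
50,0.81368
51,0.78535
52,0.759091
53,0.734711
54,0.712041
55,0.690927
56,0.671234
57,0.652841
58,0.635638
59,0.619526
60,0.604416
61,0.590228
62,0.57689
63,0.564334
64,0.552503
65,0.541341
66,0.530798
67,0.520831
68,0.511396
69,0.502458
70,0.49398
71,0.485932
72,0.478285
73,0.471011
74,0.464087
75,0.457489
76,0.451197
77,0.445192
78,0.439455
79,0.43397
80,0.428722
81,0.423697
82,0.418882
83,0.414263
84,0.409831
85,0.405575
86,0.401484
87,0.397549
88,0.393763
89,0.390116
90,0.386602
91,0.383214
92,0.379945
93,0.376788
94,0.373739
95,0.370791
96,0.36794
97,0.365182
98,0.36251
99,0.359922
100,0.357414
101,0.354981
102,0.352621
103,0.350329
104,0.348103
105,0.34594
106,0.343837
107,0.341792
108,0.339802
109,0.337864
110,0.335976
111,0.334137
112,0.332345
113,0.330596
114,0.328891
115,0.327226
116,0.3256
117,0.324013
118,0.322461
119,0.320945
120,0.319462
121,0.318011
122,0.316592
123,0.315202
124,0.313842
125,0.312509
126,0.311203
127,0.309924
128,0.308669
129,0.307438
130,0.306231
131,0.305046
132,0.303883
133,0.302742
134,0.30162
135,0.300519
136,0.299436
137,0.298372
138,0.297326
139,0.296297
140,0.295286
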