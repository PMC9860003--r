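"energy_keV","mu_per_cm"
1,2654.986557
2,332.058721
3,98.536142
4,41.691222
5,21.447773
6,12.499411
7,7.947873
8,5.392337
9,3.848129
10,2.860477
11,2.19952
12,1.740531
13,1.411827
14,1.170215
15,0.988607
16,0.849427
17,0.740934
18,0.65508
19,0.586223
20,0.530329
21,0.484458
22,0.446439
23,0.414639
24,0.387818
25,0.365022
26,0.345507
27,0.328689
28,0.314105
29,0.301383
30,0.290225
31,0.280387
32,0.27167
33,0.263911
34,0.256972
35,0.250742
36,0.245124
37,0.24004
38,0.235421
39,0.23121
40,0.227357
41,0.223821
42,0.220565
43,0.217558
44,0.214772
45,0.212185
46,0.209775
47,0.207525
48,0.205418
49,0.20344
50,0.20158
51,0.199826
52,0.198169
53,0.1966
54,0.195112
55,0.193697
56,0.192349
57,0.191063
58,0.189834
59,0.188658
60,0.18753
61,0.186447
62,0.185405
63,0.184402
64,0.183435
65,0.182501
66,0.181598
67,0.180725
68,0.179878
69,0.179057
70,0.178259
71,0.177484
72,0.17673
73,0.175996
74,0.17528
75,0.174582
76,0.1739
77,0.173235
78,0.172584
79,0.171947
80,0.171324
81,0.170714
82,0.170115
83,0.169529
84,0.168953
85,0.168388
86,0.167833
87,0.167287
88,0.166751
89,0.166223
90,0.165704
91,0.165193
92,0.16469
93,0.164195
94,0.163706
95,0.163225
96,0.16275
97,0.162282
98,0.16182
99,0.161363
100,0.160913
101,0.160469
102,0.160029
103,0.159596
104,0.159167
105,0.158743
106,0.158324
107,0.15791
108,0.1575
109,0.157095
110,0.156694
111,0.156297
112,0.155904
113,0.155515
114,0.15513
115,0.154749
116,0.154372
117,0.153998
118,0.153628
119,0.153261
120,0.152897
121,0.152537
122,0.15218
123,0.151826
124,0.151475
125,0.151127
126,0.150782
127,0.15044
128,0.150101
129,0.149765
130,0.149431
131,0.1491
132,0.148771
133,0.148446
134,0.148122
135,0.147802
136,0.147483
137,0.147167
138,0.146854
139,0.146542
140,0.146233
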