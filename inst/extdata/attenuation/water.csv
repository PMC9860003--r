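"energy_keV","mu_per_cm"
1,4696.414552
2,587.246656
3,174.154934
4,73.599072
5,37.789777
6,21.961043
7,13.910113
8,9.390027
9,6.658935
10,4.912363
11,3.743698
12,2.932299
13,2.351367
14,1.92449
15,1.603752
16,1.358064
17,1.166656
18,1.01529
19,0.893987
20,0.795608
21,0.714957
22,0.648189
23,0.59242
24,0.545455
25,0.505603
26,0.471552
27,0.442268
28,0.416931
29,0.394885
30,0.3756
31,0.358647
32,0.343673
33,0.330388
34,0.318553
35,0.307965
36,0.298459
37,0.289892
38,0.282144
39,0.275114
40,0.268715
41,0.262872
42,0.257521
43,0.252607
44,0.248082
45,0.243904
46,0.240037
47,0.236448
48,0.23311
49,0.229998
50,0.22709
51,0.224368
52,0.221813
53,0.219411
54,0.217148
55,0.215013
56,0.212994
57,0.211081
58,0.209266
59,0.207542
60,0.2059
61,0.204335
62,0.20284
63,0.201411
64,0.200043
65,0.198731
66,0.197472
67,0.196261
68,0.195096
69,0.193973
70,0.192889
71,0.191843
72,0.190832
73,0.189853
74,0.188905
75,0.187986
76,0.187094
77,0.186227
78,0.185385
79,0.184565
80,0.183767
81,0.182989
82,0.182231
83,0.181491
84,0.180768
85,0.180062
86,0.179372
87,0.178696
88,0.178035
89,0.177388
90,0.176753
91,0.176131
92,0.17552
93,0.174921
94,0.174333
95,0.173756
96,0.173188
97,0.17263
98,0.172081
99,0.171541
100,0.171009
101,0.170486
102,0.169971
103,0.169463
104,0.168962
105,0.168469
106,0.167983
107,0.167503
108,0.167029
109,0.166562
110,0.166101
111,0.165646
112,0.165196
113,0.164752
114,0.164313
115,0.163879
116,0.16345
117,0.163026
118,0.162607
119,0.162192
120,0.161782
121,0.161376
122,0.160975
123,0.160577
124,0.160184
125,0.159795
126,0.159409
127,0.159028
128,0.158649
129,0.158275
130,0.157904
131,0.157536
132,0.157172
133,0.156811
134,0.156453
135,0.156099
136,0.155747
137,0.155399
138,0.155053
139,0.154711
140,0.154371
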