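"energy_keV","mu_per_cm"
1,4514.127434
2,564.473496
3,167.417518
4,70.765053
5,36.345753
6,21.131389
7,13.392903
8,9.048198
9,6.42304
10,4.744185
11,3.620804
12,2.840821
13,2.282359
14,1.871973
15,1.563607
16,1.327378
17,1.143322
18,0.997755
19,0.881084
20,0.786448
21,0.708853
22,0.644603
23,0.590925
24,0.545709
25,0.507333
26,0.474532
27,0.446313
28,0.421889
29,0.400629
30,0.382024
31,0.36566
32,0.3512
33,0.338363
34,0.32692
35,0.316678
36,0.307475
37,0.299175
38,0.291664
39,0.284843
40,0.278628
41,0.272949
42,0.267744
43,0.262959
44,0.258548
45,0.254472
46,0.250694
47,0.247185
48,0.243917
49,0.240867
50,0.238014
51,0.235339
52,0.232826
53,0.230461
54,0.228229
55,0.226121
56,0.224124
57,0.222231
58,0.220432
59,0.21872
60,0.217088
61,0.21553
62,0.214041
63,0.212615
64,0.211247
65,0.209934
66,0.208672
67,0.207457
68,0.206287
69,0.205157
70,0.204066
71,0.203011
72,0.20199
73,0.201
74,0.20004
75,0.199109
76,0.198203
77,0.197323
78,0.196466
79,0.195632
80,0.194818
81,0.194025
82,0.19325
83,0.192493
84,0.191754
85,0.19103
86,0.190322
87,0.189629
88,0.188949
89,0.188283
90,0.18763
91,0.186989
92,0.18636
93,0.185742
94,0.185134
95,0.184537
96,0.18395
97,0.183373
98,0.182804
99,0.182244
100,0.181693
101,0.18115
102,0.180615
103,0.180087
104,0.179567
105,0.179054
106,0.178547
107,0.178047
108,0.177554
109,0.177067
110,0.176586
111,0.17611
112,0.175641
113,0.175177
114,0.174718
115,0.174264
116,0.173816
117,0.173372
118,0.172933
119,0.172499
120,0.172069
121,0.171644
122,0.171223
123,0.170806
124,0.170393
125,0.169985
126,0.16958
127,0.169179
128,0.168782
129,0.168388
130,0.167998
131,0.167611
132,0.167228
133,0.166849
134,0.166472
135,0.166099
136,0.165729
137,0.165362
138,0.164998
139,0.164637
140,0.164278
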