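"energy_keV","mu_per_cm"
1,3421.581877
2,427.923209
3,126.972505
4,53.714028
5,27.625468
6,16.093379
7,10.227671
8,6.934296
9,4.944263
10,3.671488
11,2.819739
12,2.228273
13,1.804712
14,1.493389
15,1.259395
16,1.08008
17,0.940312
18,0.82972
19,0.741032
20,0.669048
21,0.609983
22,0.561034
23,0.520102
24,0.485585
25,0.456255
26,0.431152
27,0.409525
28,0.390777
29,0.374428
30,0.360094
31,0.347461
32,0.336272
33,0.326317
34,0.317419
35,0.309434
36,0.302238
37,0.295728
38,0.289818
39,0.284434
40,0.279511
41,0.274995
42,0.27084
43,0.267006
44,0.263457
45,0.260163
46,0.257097
47,0.254236
48,0.25156
49,0.249051
50,0.246693
51,0.244471
52,0.242373
53,0.240389
54,0.238508
55,0.236722
56,0.235022
57,0.233401
58,0.231854
59,0.230374
60,0.228956
61,0.227596
62,0.226289
63,0.225031
64,0.223819
65,0.22265
66,0.22152
67,0.220428
68,0.219371
69,0.218345
70,0.217351
71,0.216385
72,0.215446
73,0.214532
74,0.213641
75,0.212774
76,0.211927
77,0.211101
78,0.210293
79,0.209504
80,0.208732
81,0.207975
82,0.207235
83,0.206509
84,0.205797
85,0.205098
86,0.204412
87,0.203738
88,0.203076
89,0.202425
90,0.201785
91,0.201155
92,0.200535
93,0.199924
94,0.199323
95,0.19873
96,0.198145
97,0.197569
98,0.197001
99,0.19644
100,0.195887
101,0.19534
102,0.194801
103,0.194268
104,0.193741
105,0.193221
106,0.192707
107,0.192199
108,0.191696
109,0.191199
110,0.190707
111,0.190221
112,0.189739
113,0.189263
114,0.188791
115,0.188324
116,0.187862
117,0.187404
118,0.186951
119,0.186502
120,0.186057
121,0.185616
122,0.185179
123,0.184746
124,0.184317
125,0.183891
126,0.183469
127,0.183051
128,0.182636
129,0.182225
130,0.181817
131,0.181413
132,0.181011
133,0.180613
134,0.180218
135,0.179827
136,0.179438
137,0.179052
138,0.178669
139,0.178289
140,0.177911
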