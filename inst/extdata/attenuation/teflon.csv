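"energy_keV","mu_per_cm"
1,12237.685117
2,1530.115517
3,453.691576
4,191.665998
5,98.355448
6,57.109755
7,36.131273
8,24.353373
9,17.237184
10,12.686433
11,9.641572
12,7.527662
13,6.014291
14,4.902353
15,4.066984
16,3.427175
17,2.928802
18,2.534768
19,2.219065
20,1.963096
21,1.753317
22,1.579713
23,1.434765
24,1.312752
25,1.209276
26,1.12091
27,1.044961
28,0.979295
29,0.922201
30,0.8723
31,0.828471
32,0.789797
33,0.755521
34,0.725018
35,0.697766
36,0.673327
37,0.651332
38,0.63147
39,0.613475
40,0.597121
41,0.582215
42,0.568588
43,0.556097
44,0.544616
45,0.534037
46,0.524265
47,0.515217
48,0.506819
49,0.499008
50,0.491727
51,0.484926
52,0.47856
53,0.472589
54,0.46698
55,0.461699
56,0.456719
57,0.452015
58,0.447564
59,0.443345
60,0.43934
61,0.435532
62,0.431907
63,0.42845
64,0.42515
65,0.421994
66,0.418972
67,0.416076
68,0.413296
69,0.410625
70,0.408055
71,0.40558
72,0.403194
73,0.400891
74,0.398666
75,0.396515
76,0.394432
77,0.392414
78,0.390458
79,0.388558
80,0.386714
81,0.384921
82,0.383176
83,0.381478
84,0.379823
85,0.37821
86,0.376636
87,0.3751
88,0.373599
89,0.372132
90,0.370697
91,0.369293
92,0.367919
93,0.366573
94,0.365253
95,0.36396
96,0.362691
97,0.361445
98,0.360222
99,0.359021
100,0.357841
101,0.35668
102,0.355539
103,0.354417
104,0.353312
105,0.352224
106,0.351154
107,0.350099
108,0.349059
109,0.348035
110,0.347024
111,0.346028
112,0.345046
113,0.344076
114,0.343119
115,0.342174
116,0.341241
117,0.34032
118,0.33941
119,0.338511
120,0.337622
121,0.336744
122,0.335875
123,0.335016
124,0.334167
125,0.333327
126,0.332496
127,0.331674
128,0.33086
129,0.330054
130,0.329257
131,0.328467
132,0.327686
133,0.326911
134,0.326145
135,0.325385
136,0.324633
137,0.323887
138,0.323148
139,0.322416
140,0.32169
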