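"energy_keV","mass_atten_cm2_per_g"
1,81857.899218
2,12597.502304
3,4215.502619
4,1938.807292
5,1061.470339
6,648.874634
7,428.016327
8,298.505918
9,217.234266
10,163.488756
11,126.430308
12,99.992064
13,80.588352
14,66.002448
15,54.811125
16,46.070659
17,39.137612
18,33.562499
19,29.024544
20,25.290442
21,22.187609
22,19.586426
23,17.388191
24,15.516805
25,13.912919
26,12.529767
27,11.33014
28,10.284174
29,9.367696
30,8.561
31,7.847899
32,7.215013
33,6.651214
34,33.741814
35,31.212361
36,28.936709
37,26.883361
38,25.025439
39,23.339907
40,21.806941
41,20.409416
42,19.132483
43,17.963223
44,16.890358
45,15.90401
46,14.995504
47,14.157198
48,13.382339
49,12.664948
50,11.999716
51,11.381916
52,10.807331
53,10.272191
54,9.773118
55,9.307077
56,8.871338
57,8.46344
58,8.081161
59,7.722489
60,7.385601
61,7.068843
62,6.77071
63,6.489832
64,6.224957
65,5.974945
66,5.738751
67,5.515417
68,5.304067
69,5.103894
70,4.914158
71,4.734175
72,4.563317
73,4.401002
74,4.246696
75,4.099902
76,3.96016
77,3.827045
78,3.700163
79,3.579146
80,3.463654
81,3.353369
82,3.247997
83,3.147262
84,3.050907
85,2.958693
86,2.870396
87,2.785806
88,2.704727
89,2.626976
90,2.552381
91,2.480781
92,2.412023
93,2.345966
94,2.282475
95,2.221426
96,2.162699
97,2.106184
98,2.051775
99,1.999373
100,1.948885
101,1.900222
102,1.853301
103,1.808044
104,1.764375
105,1.722225
106,1.681526
107,1.642216
108,1.604234
109,1.567524
110,1.532032
111,1.497707
112,1.4645
113,1.432365
114,1.401259
115,1.371139
116,1.341966
117,1.313703
118,1.286312
119,1.259762
120,1.234017
121,1.209049
122,1.184826
123,1.16132
124,1.138506
125,1.116356
126,1.094847
127,1.073955
128,1.053657
129,1.033932
130,1.014759
131,0.996119
132,0.977993
133,0.960363
134,0.943211
135,0.926522
136,0.910279
137,0.894467
138,0.879071
139,0.864078
140,0.849475
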