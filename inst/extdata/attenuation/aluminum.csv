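"energy_keV","mu_per_cm"
1,69553.111999
2,8694.591585
3,2576.53748
4,1087.272824
5,556.932355
6,322.512427
7,203.285009
8,136.350785
9,95.912222
10,70.054737
11,52.756197
12,40.748826
13,32.154664
14,25.842047
15,21.101298
16,17.471982
17,14.646479
18,12.413938
19,10.626546
20,9.178591
21,7.993112
22,7.013172
23,6.196038
24,5.509208
25,4.927668
26,4.431951
27,4.006757
28,3.639943
29,3.321794
30,3.044472
31,2.801606
32,2.587983
33,2.399307
34,2.232021
35,2.083156
36,1.950228
37,1.831143
38,1.724128
39,1.627677
40,1.540504
41,1.461507
42,1.389736
43,1.324372
44,1.264705
45,1.210116
46,1.160067
47,1.114087
48,1.07176
49,1.032724
50,0.996656
51,0.963272
52,0.93232
53,0.903575
54,0.876838
55,0.851931
56,0.828693
57,0.806981
58,0.786668
59,0.767636
60,0.749782
61,0.733012
62,0.717239
63,0.702388
64,0.688387
65,0.675172
66,0.662686
67,0.650876
68,0.639693
69,0.629092
70,0.619034
71,0.609481
72,0.600399
73,0.591757
74,0.583526
75,0.575678
76,0.568191
77,0.56104
78,0.554206
79,0.547668
80,0.541409
81,0.535413
82,0.529663
83,0.524146
84,0.518848
85,0.513756
86,0.50886
87,0.504148
88,0.499611
89,0.495238
90,0.491022
91,0.486954
92,0.483026
93,0.479231
94,0.475563
95,0.472014
96,0.46858
97,0.465255
98,0.462033
99,0.458909
100,0.45588
101,0.452939
102,0.450084
103,0.447311
104,0.444615
105,0.441994
106,0.439444
107,0.436961
108,0.434544
109,0.432189
110,0.429894
111,0.427656
112,0.425473
113,0.423343
114,0.421263
115,0.419231
116,0.417247
117,0.415307
118,0.41341
119,0.411555
120,0.409739
121,0.407962
122,0.406222
123,0.404518
124,0.402848
125,0.401211
126,0.399607
127,0.398033
128,0.396489
129,0.394973
130,0.393486
131,0.392026
132,0.390591
133,0.389182
134,0.387797
135,0.386436
136,0.385097
137,0.383781
138,0.382486
139,0.381212
140,0.379958
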