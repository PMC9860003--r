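"energy_keV","mass_atten_cm2_per_g"
1,105633.0961
2,16256.33631
3,5439.823649
4,2501.872856
5,1369.717627
6,837.285596
7,552.280206
8,385.154288
9,280.27785
10,210.922392
11,163.100674
12,128.98375
13,103.944501
14,85.12237
15,70.680758
16,59.401842
17,50.4553
18,43.261096
19,37.405286
20,32.586802
21,28.582935
22,25.226419
23,22.389884
24,19.975126
25,17.905563
26,16.120843
27,14.572951
28,13.223347
29,12.040841
30,11
31,10.079937
32,9.263386
33,8.535986
34,7.885724
35,7.302493
36,6.777749
37,6.304236
38,5.87576
39,5.487011
40,5.133422
41,4.811046
42,4.516462
43,4.246692
44,3.999139
45,3.771524
46,3.56185
47,3.368355
48,3.189484
49,3.023857
50,2.870253
51,13.348051
52,12.672866
53,12.044037
54,11.457594
55,10.90997
56,10.397958
57,9.918664
58,9.469478
59,9.048035
60,8.652193
61,8.280007
62,7.92971
63,7.599689
64,7.288476
65,6.99473
66,6.717222
67,6.454828
68,6.206516
69,5.97134
70,5.748428
71,5.536979
72,5.336252
73,5.145566
74,4.964291
75,4.791843
76,4.627684
77,4.471312
78,4.322264
79,4.180108
80,4.044446
81,3.914902
82,3.791132
83,3.67281
84,3.559636
85,3.451328
86,3.347623
87,3.248274
88,3.153051
89,3.061739
90,2.974135
91,2.89005
92,2.809305
93,2.731733
94,2.657178
95,2.585492
96,2.516534
97,2.450175
98,2.386291
99,2.324765
100,2.265488
101,2.208356
102,2.15327
103,2.100139
104,2.048875
105,1.999395
106,1.951621
107,1.905478
108,1.860896
109,1.817808
110,1.776151
111,1.735865
112,1.696893
113,1.659181
114,1.622677
115,1.587332
116,1.5531
117,1.519936
118,1.487798
119,1.456646
120,1.426441
121,1.397148
122,1.368731
123,1.341157
124,1.314395
125,1.288414
126,1.263185
127,1.23868
128,1.214874
129,1.191741
130,1.169257
131,1.147398
132,1.126143
133,1.105471
134,1.085361
135,1.065794
136,1.046751
137,1.028214
138,1.010167
139,0.992593
140,0.975475
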