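# Synthetic 120-kVp tungsten-anode spectrum (relative fluence per 1-keV bin)
# Kramers continuum + W K lines, 2.5 mm Al inherent filtration.
# Reference beam for conventional radiography; apply added Al filtration
# (e.g. 4.3 mm) with filter_spectrum()/tungsten_spectrum().
# energy_keV relative_fluence
10	1.98547e-08
11	1.35614e-06
12	2.52436e-05
13	0.00020259
14	0.000925211
15	0.00286338
16	0.00667155
17	0.0127763
18	0.0211668
19	0.0314503
20	0.0430065
21	0.0542776
22	0.0654506
23	0.0761105
24	0.0859616
25	0.0948178
26	0.102584
27	0.109235
28	0.114793
29	0.119317
30	0.122882
31	0.124517
32	0.125544
33	0.126038
34	0.126065
35	0.125688
36	0.124962
37	0.123938
38	0.12266
39	0.121168
40	0.119496
41	0.117216
42	0.114887
43	0.112521
44	0.110131
45	0.107727
46	0.105317
47	0.10291
48	0.10051
49	0.0981251
50	0.0957581
51	0.0932339
52	0.0907591
53	0.0883335
54	0.085957
55	0.0836289
56	0.081349
57	0.0791164
58	0.579001
59	1
60	0.0726957
61	0.0705525
62	0.0684633
63	0.0664261
64	0.0644392
65	0.0625008
66	0.0606092
67	0.36107
68	0.0569603
69	0.124668
70	0.0534804
71	0.0518004
72	0.0501586
73	0.0485537
74	0.0469846
75	0.0454501
76	0.0439492
77	0.0424808
78	0.0410438
79	0.0396373
80	0.0382604
81	0.0368904
82	0.0355505
83	0.0342398
84	0.0329572
85	0.0317019
86	0.030473
87	0.0292696
88	0.0280911
89	0.0269366
90	0.0258053
91	0.0246967
92	0.0236099
93	0.0225444
94	0.0214996
95	0.0204747
96	0.0194694
97	0.018483
98	0.0175149
99	0.0165647
100	0.0156319
101	0.0147121
102	0.0138092
103	0.0129229
104	0.0120527
105	0.0111981
106	0.0103587
107	0.00953409
108	0.00872392
109	0.00792777
110	0.00714529
111	0.00637613
112	0.00561993
113	0.00487637
114	0.00414514
115	0.00342593
116	0.00271843
117	0.00202236
118	0.00133744
119	0.000663411
120	0
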