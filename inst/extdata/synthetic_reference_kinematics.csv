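"percent_cycle","hip_deg","knee_deg","ankle_deg"
0,30,5,0
1,29.951,5.039,0.502
2,29.803,5.158,1.003
3,29.557,5.354,1.499
4,29.215,5.628,1.99
5,28.776,5.979,2.472
6,28.244,6.404,2.945
7,27.621,6.903,3.406
8,26.908,7.473,3.854
9,26.108,8.113,4.287
10,25.225,8.819,4.702
11,24.263,9.588,5.099
12,23.224,10.418,5.476
13,22.114,11.306,5.832
14,20.936,12.247,6.164
15,19.695,13.238,6.472
16,18.396,14.275,6.755
17,17.044,15.353,7.01
18,15.644,16.469,7.239
19,14.203,17.617,7.438
20,12.725,18.792,7.608
21,11.217,19.99,7.749
22,9.685,21.206,7.858
23,8.133,22.434,7.937
24,6.57,23.669,7.984
25,5,24.905,8
26,3.43,26.137,7.984
27,1.867,27.36,7.937
28,0.315,28.569,7.858
29,-1.217,29.757,7.749
30,-2.725,30.919,7.608
31,-4.203,32.052,7.438
32,-5.644,33.149,7.239
33,-7.044,34.207,7.01
34,-8.396,35.222,6.755
35,-9.695,36.191,6.472
36,-10.936,37.11,6.164
37,-12.114,37.98,5.831
38,-13.224,38.797,5.475
39,-14.263,39.563,5.096
40,-15.225,40.28,4.696
41,-16.108,40.949,4.274
42,-16.908,41.576,3.831
43,-17.621,42.166,3.364
44,-18.244,42.728,2.869
45,-18.776,43.271,2.341
46,-19.215,43.808,1.77
47,-19.557,44.353,1.142
48,-19.803,44.923,0.441
49,-19.951,45.536,-0.353
50,-20,46.214,-1.265
51,-19.951,46.979,-2.314
52,-19.803,47.855,-3.518
53,-19.557,48.864,-4.884
54,-19.215,50.028,-6.404
55,-18.776,51.366,-8.053
56,-18.244,52.894,-9.782
57,-17.621,54.619,-11.526
58,-16.908,56.541,-13.2
59,-16.108,58.65,-14.712
60,-15.225,60.923,-15.975
61,-14.263,63.325,-16.913
62,-13.224,65.807,-17.476
63,-12.114,68.307,-17.646
64,-10.936,70.753,-17.437
65,-9.695,73.061,-16.898
66,-8.396,75.143,-16.1
67,-7.044,76.909,-15.13
68,-5.644,78.272,-14.076
69,-4.203,79.154,-13.019
70,-2.725,79.487,-12.023
71,-1.217,79.224,-11.133
72,0.315,78.335,-10.374
73,1.867,76.815,-9.749
74,3.43,74.68,-9.249
75,5,71.971,-8.856
76,6.57,68.745,-8.545
77,8.133,65.081,-8.294
78,9.685,61.066,-8.078
79,11.217,56.797,-7.88
80,12.725,52.371,-7.684
81,14.203,47.886,-7.481
82,15.644,43.431,-7.262
83,17.044,39.086,-7.023
84,18.396,34.918,-6.761
85,19.695,30.982,-6.475
86,20.936,27.319,-6.166
87,22.114,23.955,-5.832
88,23.224,20.904,-5.477
89,24.263,18.171,-5.1
90,25.225,15.752,-4.702
91,26.108,13.635,-4.287
92,26.908,11.805,-3.854
93,27.621,10.242,-3.406
94,28.244,8.927,-2.945
95,28.776,7.839,-2.472
96,29.215,6.958,-1.99
97,29.557,6.265,-1.499
98,29.803,5.743,-1.003
99,29.951,5.376,-0.502
100,30,5.151,0
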