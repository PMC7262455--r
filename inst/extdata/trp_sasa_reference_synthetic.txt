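# synthetic tryptophan side-chain SASA reference (A^2), sorted
# 600 values drawn from a buried + exposed mixture; NOT an
# empirical database -- a stand-in for demonstration and examples
0.48
0.49
0.49
0.84
0.93
0.97
1.13
1.22
1.25
1.33
1.43
1.45
1.62
1.96
2.17
2.31
2.34
2.34
2.36
2.37
2.37
2.52
2.52
2.53
2.54
2.60
2.70
2.80
2.85
2.95
2.97
3.01
3.17
3.29
3.29
3.33
3.36
3.39
3.43
3.48
3.50
3.59
3.70
3.77
3.93
3.96
3.98
4.01
4.03
4.05
4.12
4.16
4.17
4.21
4.34
4.39
4.40
4.44
4.54
4.63
4.67
4.92
5.04
5.05
5.11
5.11
5.29
5.31
5.39
5.41
5.43
5.45
5.49
5.50
5.55
5.56
5.64
5.78
5.85
5.96
6.08
6.17
6.28
6.39
6.39
6.58
6.61
6.62
6.63
6.64
6.64
6.79
6.86
6.95
7.16
7.33
7.41
7.52
7.54
7.55
7.58
7.67
7.89
7.93
8.30
8.37
8.44
8.58
8.59
8.71
8.83
8.85
8.86
9.11
9.23
9.29
9.31
9.38
9.63
9.76
9.88
9.93
9.95
10.08
10.17
10.18
10.19
10.25
10.30
10.33
10.42
10.52
10.69
10.84
10.88
10.88
10.88
10.91
11.03
11.14
11.16
11.28
11.29
11.31
11.38
11.66
11.69
11.74
11.84
11.88
11.89
11.91
12.08
12.39
12.46
12.46
13.07
13.19
13.21
13.50
13.63
13.70
13.83
13.90
14.02
14.04
14.12
14.15
14.26
14.31
14.32
14.53
14.57
14.59
14.88
14.96
15.02
15.18
15.27
15.29
15.36
15.60
16.21
16.48
16.97
17.01
17.06
17.08
17.36
17.43
17.95
17.97
18.19
18.29
18.31
18.35
18.36
18.36
18.59
18.68
18.92
19.02
19.03
19.04
19.49
19.63
19.71
19.93
19.96
19.99
20.22
20.60
20.66
20.80
20.88
20.98
21.11
21.25
21.26
21.38
21.38
21.50
21.65
21.70
21.80
21.87
22.11
22.17
22.27
22.89
22.93
23.03
23.06
23.06
23.13
23.17
23.24
23.40
23.45
23.99
24.58
24.64
24.75
24.77
24.78
24.87
24.94
24.94
25.17
25.50
25.55
25.64
25.80
25.88
25.95
26.31
26.47
26.50
26.55
26.87
27.00
27.06
27.33
27.66
27.72
27.94
29.51
29.61
30.12
30.46
30.54
30.57
30.63
30.75
30.77
31.07
32.15
32.73
32.74
32.94
32.95
33.40
33.93
34.07
34.11
34.38
34.49
34.63
35.17
35.36
36.52
37.05
37.06
37.47
37.97
38.83
39.00
39.88
40.04
40.07
41.32
41.52
42.33
43.00
43.68
44.20
44.95
45.34
46.20
46.76
46.97
48.14
48.29
49.76
51.01
51.50
52.45
52.56
52.60
53.31
54.06
55.66
56.69
57.94
58.45
58.49
59.27
59.54
60.23
60.75
61.06
62.22
62.74
62.79
64.29
64.43
65.78
65.84
67.18
67.37
67.64
67.65
67.97
68.31
69.41
69.68
70.81
71.50
72.51
72.63
72.82
72.95
73.90
74.55
75.79
76.45
76.68
77.00
79.70
81.05
81.74
82.92
84.16
84.51
85.20
85.61
85.82
85.95
87.14
87.21
87.67
87.70
87.88
88.90
89.62
90.34
90.64
91.22
92.05
92.15
92.61
93.38
93.81
94.14
94.38
94.40
94.68
94.90
95.49
95.72
95.82
95.86
96.21
96.49
96.58
96.90
96.96
96.96
97.44
97.44
97.86
97.94
98.03
98.06
98.39
98.40
99.54
99.66
100.11
101.04
101.24
101.26
102.41
102.81
102.87
103.54
103.78
104.54
104.63
104.94
105.32
106.05
107.53
107.85
108.37
108.41
108.48
109.65
110.83
111.17
111.56
111.97
112.21
112.62
113.21
113.62
113.88
113.91
114.13
114.30
114.68
115.06
115.48
115.63
115.84
116.24
116.77
118.09
118.39
118.75
119.55
120.52
120.58
122.48
122.76
122.85
122.87
122.98
123.73
123.74
123.74
124.49
124.88
125.42
127.07
129.27
130.23
130.37
130.39
130.44
131.54
133.19
134.39
134.44
135.41
135.63
135.66
136.46
136.66
136.76
137.48
138.04
139.32
140.96
142.76
143.61
144.34
144.41
145.24
145.78
145.92
146.55
146.94
147.10
147.36
147.57
147.66
147.85
147.89
149.75
149.83
149.95
150.80
151.48
152.34
154.73
154.94
156.21
157.68
157.85
158.55
158.68
159.31
160.02
161.40
162.18
163.74
165.31
168.20
168.31
168.68
168.86
171.72
171.72
171.98
172.86
173.28
174.87
176.24
177.56
177.76
177.99
178.00
178.06
179.14
179.38
181.65
182.63
182.95
183.14
183.46
184.30
184.57
184.88
185.70
186.46
187.28
187.65
188.97
190.43
190.85
191.49
192.73
194.41
195.05
195.30
195.57
198.71
198.85
199.02
201.33
202.76
202.96
203.92
204.55
206.50
208.65
208.68
208.93
209.33
209.49
211.90
213.86
218.21
230.37
231.64
234.92
235.97
238.12
238.43
242.79
242.84
246.41
247.58
250.32
254.33
258.03
259.10
273.25
276.12
276.60
278.51
280.00
280.00
280.00
280.00
280.00
280.00
280.00
280.00
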