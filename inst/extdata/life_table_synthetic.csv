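age,qx
60,0.00864
61,0.00951
62,0.01045
63,0.01149
64,0.01264
65,0.0139
66,0.01528
67,0.01681
68,0.01848
69,0.02033
70,0.02235
71,0.02458
72,0.02703
73,0.02972
74,0.03268
75,0.03594
76,0.03952
77,0.04346
78,0.04779
79,0.05255
80,0.05779
81,0.06355
82,0.06989
83,0.07685
84,0.08451
85,0.09293
86,0.10219
87,0.11238
88,0.12358
89,0.13589
90,0.14943
91,0.16433
92,0.1807
93,0.19871
94,0.21851
95,0.24029
96,0.26424
97,0.29057
98,0.31953
99,0.35137
100,0.38639
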