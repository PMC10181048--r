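genotype,YLD_Ahvaz,YLD_Gonbad,YLD_Zabol,YLD_Darab,SIIG_Ahvaz,rank_Ahvaz,SIIG_Gonbad,rank_Gonbad,SIIG_Zabol,rank_Zabol,SIIG_Darab,rank_Darab
1,850,3183,7138,7780,0.303,103,0.503,59,0.758,3,0.612,3
2,1200,3475,5583,5313,0.341,93,0.540,49,0.535,53,0.490,32
3,1050,4400,6708,6020,0.372,78,0.731,5,0.682,14,0.528,14
4,1100,3722,5583,5220,0.366,81,0.696,8,0.709,7,0.460,50
5,1500,3538,6694,5497,0.463,43,0.566,41,0.735,4,0.498,29
6,1150,2772,5416,3787,0.363,83,0.536,51,0.614,29,0.395,86
7,1300,3605,5291,3780,0.363,82,0.639,16,0.549,49,0.351,102
8,1150,2982,4944,4370,0.440,50,0.472,72,0.498,70,0.434,64
9,1400,2903,3930,6200,0.447,47,0.457,77,0.394,97,0.530,12
10,800,2860,3416,3053,0.266,108,0.465,74,0.372,103,0.337,106
11,1100,3408,5805,3710,0.396,64,0.571,37,0.646,19,0.402,81
12,1100,2977,4416,4283,0.328,98,0.497,63,0.474,74,0.454,52
13,1800,2752,4000,4947,0.543,19,0.420,83,0.375,102,0.450,54
14,1550,2667,4569,5170,0.460,44,0.463,75,0.458,80,0.450,55
15,1900,3135,6513,4930,0.577,11,0.500,62,0.683,13,0.465,46
16,1600,3057,6527,5390,0.486,36,0.481,68,0.703,10,0.505,25
17,1700,2787,5180,3320,0.503,29,0.544,47,0.534,55,0.331,108
18,1650,3048,7263,4367,0.539,20,0.505,56,0.722,5,0.433,65
19,1300,3418,5652,6317,0.391,67,0.489,67,0.578,39,0.563,7
20,1600,2478,4305,6300,0.473,40,0.370,98,0.413,92,0.510,21
21,1300,2782,3458,5920,0.387,69,0.467,73,0.406,93,0.509,23
22,700,3160,3555,5820,0.249,111,0.512,55,0.362,104,0.489,34
23,1000,3058,6138,5457,0.311,101,0.553,45,0.679,15,0.491,31
24,1100,3363,4500,4360,0.337,94,0.578,33,0.495,71,0.416,71
25,800,3403,5027,3683,0.250,110,0.576,35,0.558,45,0.578,6
26,600,3647,6347,4240,0.267,107,0.652,13,0.707,8,0.412,73
27,950,3638,4569,5840,0.367,80,0.618,22,0.488,72,0.501,28
28,1500,2710,4291,4420,0.413,61,0.419,84,0.435,86,0.394,87
29,1200,3667,6305,4600,0.336,95,0.577,34,0.628,24,0.425,67
30,1200,2932,4486,4000,0.355,87,0.472,71,0.467,78,0.399,85
31,1400,2882,5222,3833,0.360,86,0.428,79,0.529,58,0.362,95
32,1100,2665,3555,3617,0.296,104,0.552,46,0.422,88,0.353,101
33,1700,3255,3944,4747,0.517,25,0.493,65,0.468,77,0.423,68
34,1400,3712,2680,3737,0.433,52,0.529,52,0.330,106,0.384,90
35,1450,3905,2805,4270,0.442,49,0.591,30,0.337,105,0.407,76
36,1500,4687,4333,3170,0.474,39,0.740,4,0.520,62,0.357,98
37,2700,2997,3611,4140,0.719,1,0.425,81,0.422,89,0.405,79
38,2000,3482,4472,3063,0.648,3,0.676,9,0.574,40,0.342,105
39,1800,3067,4208,3107,0.555,18,0.568,40,0.523,61,0.306,110
40,1800,3367,4750,3540,0.583,10,0.635,20,0.608,30,0.355,99
41,1800,3720,4916,4010,0.560,15,0.617,23,0.594,32,0.385,89
42,1700,3140,3805,3227,0.537,21,0.504,57,0.446,81,0.347,104
43,1250,3502,4472,3080,0.423,55,0.543,48,0.532,57,0.326,109
44,1000,3183,5152,4667,0.386,70,0.560,43,0.563,43,0.480,39
45,1750,3302,4222,4403,0.557,17,0.492,66,0.516,67,0.460,51
46,1400,2688,5277,4420,0.431,53,0.351,99,0.616,27,0.406,78
47,1200,2622,4388,3150,0.395,65,0.389,90,0.502,69,0.333,107
48,1300,3585,4875,3993,0.416,59,0.538,50,0.580,38,0.400,83
49,1300,1888,4027,3567,0.446,48,0.232,111,0.460,79,0.351,103
50,1700,2158,3166,4330,0.483,37,0.306,106,0.380,100,0.410,75
51,1600,2713,4819,5320,0.483,38,0.503,58,0.592,33,0.486,36
52,1400,2688,5472,3983,0.416,58,0.378,94,0.667,18,0.359,97
53,1400,2663,5000,3947,0.418,56,0.399,89,0.581,37,0.378,91
54,1600,2267,7319,4137,0.514,26,0.315,103,0.773,1,0.413,72
55,1800,2307,5638,5610,0.501,31,0.382,92,0.616,28,0.540,11
56,1800,2202,6333,5997,0.534,22,0.307,105,0.761,2,0.527,15
57,1550,1660,5666,4860,0.492,32,0.298,108,0.633,23,0.436,60
58,1250,2120,5236,6410,0.374,77,0.333,101,0.564,42,0.560,8
59,1100,2142,5069,4317,0.376,75,0.370,97,0.618,25,0.399,84
60,1100,1163,3888,3337,0.346,90,0.263,109,0.377,101,0.353,100
61,1500,2083,4541,3933,0.451,45,0.332,102,0.518,64,0.412,74
62,1400,2660,5805,5430,0.393,66,0.426,80,0.674,17,0.510,22
63,2100,2090,3138,6087,0.601,8,0.315,104,0.326,107,0.518,18
64,1800,3283,3319,5323,0.567,12,0.648,15,0.417,91,0.490,33
65,1300,3142,5333,3757,0.412,62,0.528,53,0.585,35,0.377,93
66,1700,3480,3736,3970,0.532,23,0.586,31,0.420,90,0.393,88
67,1800,3452,4263,4653,0.566,13,0.570,39,0.471,75,0.454,53
68,1650,2953,4527,4600,0.491,33,0.455,78,0.516,66,0.418,70
69,1800,2937,3750,5110,0.509,28,0.408,88,0.399,94,0.466,45
70,1700,2745,5583,4260,0.490,34,0.415,85,0.635,21,0.443,57
71,2200,2048,4805,3383,0.638,4,0.256,110,0.566,41,0.377,92
72,1900,2312,4263,6017,0.591,9,0.385,91,0.446,82,0.595,5
73,1200,2690,4902,5223,0.361,84,0.495,64,0.562,44,0.552,9
74,950,3397,5180,4000,0.308,102,0.638,18,0.589,34,0.485,38
75,1450,4147,4680,4017,0.439,51,0.619,21,0.545,51,0.403,80
76,1000,3783,4763,4630,0.336,97,0.649,14,0.532,56,0.443,58
77,850,3513,5250,4550,0.275,106,0.637,19,0.557,46,0.407,77
78,850,3347,4486,5797,0.281,105,0.614,25,0.476,73,0.505,26
79,1200,3347,3583,4807,0.377,74,0.607,28,0.395,96,0.471,42
80,1000,4172,4638,5370,0.353,89,0.752,2,0.513,68,0.501,27
81,1400,3302,1944,5190,0.414,60,0.615,24,0.258,111,0.466,44
82,1200,2827,6152,4943,0.368,79,0.565,42,0.699,11,0.479,40
83,750,3143,4111,4950,0.257,109,0.638,17,0.441,83,0.462,49
84,1000,3740,3097,4847,0.342,92,0.744,3,0.399,95,0.435,61
85,900,3553,3888,5440,0.411,63,0.654,12,0.440,84,0.527,16
86,1300,3955,4250,8360,0.449,46,0.656,11,0.470,76,0.659,1
87,1500,3702,4902,7020,0.489,35,0.608,27,0.537,52,0.621,2
88,1350,2207,4944,5600,0.378,73,0.348,100,0.555,47,0.487,35
89,1200,2683,5833,4927,0.376,76,0.408,87,0.697,12,0.467,43
90,1300,2762,5986,4707,0.430,54,0.459,76,0.644,20,0.462,48
91,1300,2892,4152,450,0.418,57,0.480,70,0.438,85,0.198,111
92,1200,2583,4347,4660,0.360,85,0.423,82,0.424,87,0.435,63
93,1000,2147,3125,5700,0.355,88,0.302,107,0.297,110,0.495,30
94,800,2513,3180,6187,0.312,100,0.381,93,0.304,109,0.518,19
95,950,2257,5208,6017,0.343,91,0.372,96,0.535,54,0.509,24
96,1050,2442,6444,5260,0.326,99,0.374,95,0.712,6,0.463,47
97,1000,3682,6208,5000,0.336,96,0.609,26,0.678,16,0.474,41
98,1200,2650,5833,4803,0.381,71,0.415,86,0.603,31,0.439,59
99,1900,3548,4180,5883,0.601,7,0.713,6,0.519,63,0.513,20
100,1750,2833,4916,5160,0.501,30,0.501,61,0.516,65,0.430,66
101,1350,2807,5166,4877,0.388,68,0.501,60,0.550,48,0.448,56
102,1850,3192,5000,4267,0.509,27,0.599,29,0.527,59,0.372,94
103,2000,3752,5083,3820,0.518,24,0.662,10,0.526,60,0.359,96
104,2100,2735,6222,4933,0.613,6,0.481,69,0.617,26,0.435,62
105,2400,4242,5305,6443,0.637,5,0.761,1,0.547,50,0.526,17
106,2100,3108,3805,4220,0.560,16,0.582,32,0.391,98,0.401,82
107,2000,4103,3250,3800,0.653,2,0.706,7,0.383,99,0.422,69
108,1950,3206,6425,6957,0.562,14,0.559,44,0.706,9,0.611,4
109,1500,3450,4967,6107,0.470,42,0.570,38,0.581,36,0.529,13
110,1200,3153,5814,4671,0.380,72,0.576,36,0.635,22,0.485,37
111,1617,3217,3194,7107,0.471,41,0.519,54,0.310,108,0.544,10
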