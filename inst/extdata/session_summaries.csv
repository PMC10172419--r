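session,n_female,n_male,age_min,age_max,mean_acr_ref,mean_acr_algo,pct_decrease
1,6,3,18,70,0.0347,0.0315,9.25
2,1,9,43,85,0.0145,0.0138,5.16
3,6,3,49,78,0.0172,0.0164,5.12
4,4,8,51,82,0.0161,0.0152,5.51
5,2,6,48,85,0.0184,0.0170,7.45
6,1,7,40,84,0.0194,0.0182,6.24
7,10,2,31,77,0.0274,0.0261,5.03
8,5,5,36,78,0.0243,0.0230,5.22
9,6,6,46,84,0.0171,0.0161,5.83
10,4,6,54,90,0.0145,0.0140,3.47
11,4,4,28,84,0.0211,0.0192,9.07
12,5,6,43,76,0.0210,0.0197,6.20
13,4,7,37,88,0.0236,0.0218,7.66
14,2,7,28,75,0.0254,0.0237,6.46
15,4,4,34,85,0.0192,0.0176,8.54
16,5,3,21,75,0.0161,0.0159,1.34
17,2,7,57,80,0.0149,0.0145,2.53
18,4,4,18,75,0.0264,0.0238,9.57
19,3,5,26,83,0.0211,0.0197,6.45
20,3,8,55,84,0.0148,0.0142,4.27
21,2,7,20,75,0.0269,0.0243,9.47
22,2,6,24,74,0.0237,0.0223,5.82
23,3,7,47,81,0.0177,0.0175,0.97
24,5,3,42,84,0.0187,0.0172,8.19
25,4,8,48,85,0.0132,0.0124,6.06
26,4,5,54,73,0.0158,0.0157,0.69
27,5,2,53,83,0.0166,0.0159,4.04
28,3,5,38,81,0.0181,0.0170,5.79
29,4,6,19,81,0.0235,0.0210,10.61
30,4,7,30,82,0.0178,0.0171,4.04
31,4,4,31,84,0.0222,0.0200,10.18
32,7,5,32,79,0.0204,0.0191,6.50
33,5,4,17,86,0.0218,0.0195,10.50
34,0,9,54,77,0.0144,0.0143,1.23
35,7,4,19,82,0.0199,0.0186,6.36
36,6,4,50,76,0.0377,0.0327,13.03
37,7,5,40,89,0.0153,0.0144,5.90
38,4,5,17,78,0.0230,0.0213,7.30
39,5,5,19,79,0.0186,0.0179,3.78
40,8,5,17,81,0.0220,0.0200,9.03
41,4,7,46,88,0.0170,0.0164,3.58
42,1,11,44,81,0.0159,0.0151,5.43
43,4,6,46,84,0.0184,0.0173,5.77
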