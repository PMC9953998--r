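time,event,MARKER1,MARKER2,cohort
10,0,9.3603,2.9478,KOC_S
10,0,11.4492,2.847,KOC_S
10,0,10.7496,4.4325,KOC_S
10,0,10.7599,4.5053,KOC_S
0.346,1,9.7395,3.9697,KOC_S
10,0,10.3829,2.8226,KOC_S
2.1365,1,10.6258,4.2196,KOC_S
10,0,9.0433,4.0387,KOC_S
10,0,8.7167,4.7976,KOC_S
10,0,9.2767,4.8991,KOC_S
2.5208,1,10.6658,5.9703,KOC_S
10,0,10.3774,3.3347,KOC_S
10,0,9.0016,3.6625,KOC_S
10,0,10.8758,4.1042,KOC_S
10,0,11.059,1.8739,KOC_S
10,0,10.8715,3.2083,KOC_S
10,0,9.1024,3.9276,KOC_S
10,0,10.1129,3.3812,KOC_S
10,0,10.3154,3.9597,KOC_S
10,0,9.5926,5.1882,KOC_S
10,0,10.3586,4.7232,KOC_S
10,0,9.0787,5.2758,KOC_S
10,0,10.2521,2.8406,KOC_S
10,0,9.5608,3.9837,KOC_S
3.8346,1,9.4802,5.1267,KOC_S
10,0,9.6432,4.0192,KOC_S
10,0,10.5031,4.9452,KOC_S
10,0,11.4538,3.5722,KOC_S
1.2374,1,11.1655,5.0946,KOC_S
9.1719,1,11.6054,4.8509,KOC_S
1.8741,1,11.1935,3.2803,KOC_S
1.6046,1,10.8187,5.6775,KOC_S
4.3456,1,11.5117,5.4892,KOC_S
5.4796,1,11.6077,2.9458,KOC_S
6.5085,1,12.4411,2.0803,KOC_S
10,0,12.4812,4.5957,KOC_S
3.0915,1,11.1817,2.8377,KOC_S
10,0,11.5964,2.3253,KOC_S
7.8639,1,9.4648,3.476,KOC_S
7.7126,1,11.6066,4.7772,KOC_S
3.562,1,8.5018,6.5124,KOC_S
3.1187,1,10.8001,4.314,KOC_S
10,0,11.1902,4.1193,KOC_S
7.7455,1,12.3895,3.891,KOC_S
3.0195,1,9.7981,3.599,KOC_S
2.1098,1,11.5126,5.1125,KOC_S
0.0014,1,11.1751,2.1289,KOC_S
1.4932,1,10.5791,4.3647,KOC_S
0.8372,1,12.9899,4.826,KOC_S
7.1826,1,13.449,4.8289,KOC_S
10,0,11.7894,4.4525,KOC_S
10,0,11.8114,2.8103,KOC_S
0.3875,1,11.7761,4.459,KOC_S
3.9534,1,12.222,2.5185,KOC_S
2.5147,1,12.1746,2.3282,KOC_S
0.6484,1,12.102,4.0661,KOC_S
10,0,9.5137,3.0696,OBE_S
9.4498,1,9.1756,3.0513,OBE_S
10,0,10.0238,5.3227,OBE_S
2.0672,1,10.6699,4.1535,OBE_S
10,0,10.4712,3.0526,OBE_S
10,0,10.0345,3.4715,OBE_S
10,0,10.3676,3.4883,OBE_S
2.551,1,9.0401,4.0189,OBE_S
10,0,10.6024,5.1808,OBE_S
10,0,10.8354,2.4734,OBE_S
10,0,8.6091,4.7519,OBE_S
1.3855,1,10.4472,6.6415,OBE_S
10,0,8.5128,4.273,OBE_S
0.4074,1,11.3271,3.9869,OBE_S
10,0,11.2761,2.0484,OBE_S
6.147,1,13.5074,4.032,OBE_S
5.53,1,11.606,5.4676,OBE_S
0.9462,1,10.4187,2.0665,OBE_S
5.7248,1,10.0331,3.9874,OBE_S
10,0,10.4154,5.283,OBE_S
5.8328,1,12.0693,3.4427,OBE_S
10,0,9.187,4.8047,OBE_S
10,0,11.6024,4.0039,OBE_S
10,0,11.2198,4.19,OBE_S
7.1394,1,11.1439,1.8081,OBE_S
4.4765,1,10.5027,4.0684,OBE_S
1.213,1,11.1644,5.3045,OBE_S
10,0,11.9164,4.68,OBE_S
1.2254,1,12.2724,3.7255,OBE_S
10,0,12.0754,2.7023,OBE_S
10,0,9.6872,2.6904,SEQ_S
10,0,9.0537,3.1583,SEQ_S
10,0,10.3583,3.6801,SEQ_S
5.4883,1,10.1983,4.9755,SEQ_S
10,0,11.18,3.2189,SEQ_S
10,0,9.7645,5.0033,SEQ_S
5.662,1,11.1192,4.8009,SEQ_S
10,0,9.9399,4.3672,SEQ_S
10,0,8.5752,4.5968,SEQ_S
10,0,11.9834,2.8954,SEQ_S
10,0,10.4411,2.3314,SEQ_S
3.3672,1,11.0153,3.8344,SEQ_S
10,0,10.3375,5.274,SEQ_S
10,0,10.8192,4.4942,SEQ_S
10,0,9.6983,3.1485,SEQ_S
10,0,7.8456,4.0467,SEQ_S
10,0,9.7594,3.7557,SEQ_S
10,0,9.8945,4.4764,SEQ_S
10,0,11.3511,3.6194,SEQ_S
10,0,10.0817,3.0859,SEQ_S
10,0,11.2686,3.9815,SEQ_S
10,0,9.2296,6.2706,SEQ_S
8.212,1,9.8811,4.7852,SEQ_S
8.8278,1,11.2694,5.6495,SEQ_S
1.4845,1,11.6624,5.3704,SEQ_S
10,0,12.0897,4.0658,SEQ_S
6.5769,1,11.4709,4.62,SEQ_S
10,0,12.5683,5.0929,SEQ_S
7.8297,1,10.1483,4.0495,SEQ_S
2.146,1,12.1814,3.329,SEQ_S
10,0,12.2116,4.1756,SEQ_S
7.1289,1,11.1218,4.5421,SEQ_S
5.2063,1,10.8639,2.6272,SEQ_S
1.0069,1,11.0826,4.315,SEQ_S
4.5267,1,10.6134,5.6695,SEQ_S
2.654,1,12.2658,3.2007,SEQ_S
10,0,10.5338,5.3738,SEQ_S
10,0,10.2094,3.0389,SEQ_S
10,0,11.6705,4.096,SEQ_S
1.2795,1,10.8718,4.9911,SEQ_S
0.3039,1,10.9663,4.112,SEQ_S
10,0,11.2631,4.855,SEQ_S
4.0886,1,12.4991,5.2735,SEQ_S
3.339,1,10.3466,4.4894,SEQ_S
0.0599,1,10.445,3.8947,SEQ_S
2.7591,1,12.6779,5.6257,SEQ_S
5.8917,1,10.8382,3.0811,SEQ_S
10,0,11.5893,5.299,SEQ_S
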