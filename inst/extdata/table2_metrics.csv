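dataset,method,rmse,mae,r2
D1,KNN,4.1878,3.1845,0.2055
D1,R-KNN,3.7979,2.7844,0.6291
D1,Gaussian,3.7976,2.7844,0.6287
D1,Epanechnikov,3.7975,2.7846,0.6288
D1,Uniform,3.7979,2.7844,0.6304
D1,Triangular,3.7949,2.7828,0.6284
D1,Quartic,3.7971,2.7848,0.6275
D1,Tricube,3.7982,2.7856,0.6273
D2,KNN,2.8320,2.0736,0.2579
D2,R-KNN,2.5161,1.7633,0.6392
D2,Gaussian,2.4875,1.7457,0.6434
D2,Epanechnikov,2.4873,1.7445,0.6432
D2,Uniform,2.4878,1.7450,0.6434
D2,Triangular,2.4852,1.7429,0.6436
D2,Quartic,2.4867,1.7441,0.6431
D2,Tricube,2.4874,1.7447,0.6429
D3,KNN,31.9275,27.5843,0.1452
D3,R-KNN,32.0872,27.8724,0.1352
D3,Gaussian,32.0903,27.8737,0.1348
D3,Epanechnikov,32.0473,27.8755,0.1341
D3,Uniform,32.0335,27.8629,0.1352
D3,Triangular,32.0549,27.8799,0.1333
D3,Quartic,32.0614,27.8793,0.1330
D3,Tricube,32.0629,27.8772,0.1331
D4,KNN,0.103200,0.088300,0.7049
D4,R-KNN,0.100200,0.081800,0.7194
D4,Gaussian,0.100027,0.082446,0.7202
D4,Epanechnikov,0.099257,0.081848,0.7247
D4,Uniform,0.099807,0.082148,0.7224
D4,Triangular,0.098940,0.081626,0.7260
D4,Quartic,0.098797,0.081580,0.7265
D4,Tricube,0.098812,0.081613,0.7265
D5,KNN,0.1811,0.1302,0.4476
D5,R-KNN,0.1749,0.1242,0.4726
D5,Gaussian,0.1745,0.1239,0.4752
D5,Epanechnikov,0.1733,0.1228,0.4818
D5,Uniform,0.1749,0.1242,0.4726
D5,Triangular,0.1729,0.1223,0.4844
D5,Quartic,0.1723,0.1217,0.4879
D5,Tricube,0.1722,0.1216,0.4886
D6,KNN,0.1391,0.1028,0.2026
D6,R-KNN,0.1321,0.0970,0.2691
D6,Gaussian,0.1320,0.0969,0.2696
D6,Epanechnikov,0.1320,0.0969,0.2702
D6,Uniform,0.1321,0.0970,0.2691
D6,Triangular,0.1318,0.0967,0.2720
D6,Quartic,0.1319,0.0968,0.2713
D6,Tricube,0.1319,0.0969,0.2705
D7,KNN,0.1461,0.1233,0.8585
D7,R-KNN,0.1454,0.1225,0.8563
D7,Gaussian,0.1444,0.1223,0.8566
D7,Epanechnikov,0.1406,0.1188,0.8646
D7,Uniform,0.1429,0.1213,0.8635
D7,Triangular,0.1400,0.1180,0.8651
D7,Quartic,0.1389,0.1171,0.8652
D7,Tricube,0.1387,0.1169,0.8655
D8,KNN,0.0290436,0.0203419,0.0320561
D8,R-KNN,0.0280759,0.0195862,0.0519505
D8,Gaussian,0.0280758,0.0195861,0.0519602
D8,Epanechnikov,0.0280756,0.0195860,0.0520021
D8,Uniform,0.0280759,0.0195862,0.0519789
D8,Triangular,0.0280745,0.0195852,0.0520842
D8,Quartic,0.0280753,0.0195857,0.0520282
D8,Tricube,0.0280756,0.0195860,0.0520045
D9,KNN,4.9607,3.6138,0.9043
D9,R-KNN,4.8846,3.5413,0.9189
D9,Gaussian,4.8699,3.5324,0.9192
D9,Epanechnikov,4.8446,3.5176,0.9197
D9,Uniform,4.8839,3.5412,0.9189
D9,Triangular,4.8103,3.4896,0.9205
D9,Quartic,4.8101,3.4962,0.9204
D9,Tricube,4.8204,3.5057,0.9202
D10,KNN,0.9900,0.7839,0.0421
D10,R-KNN,0.9532,0.7586,0.1469
D10,Gaussian,0.9532,0.7586,0.1464
D10,Epanechnikov,0.9525,0.7580,0.1440
D10,Uniform,0.9526,0.7581,0.1468
D10,Triangular,0.9526,0.7579,0.1436
D10,Quartic,0.9525,0.7579,0.1407
D10,Tricube,0.9524,0.7578,0.1382
D11,KNN,0.3953,0.3048,0.8877
D11,R-KNN,0.3802,0.2838,0.8999
D11,Gaussian,0.3799,0.2837,0.9000
D11,Epanechnikov,0.3760,0.2818,0.9023
D11,Uniform,0.3767,0.2821,0.9020
D11,Triangular,0.3754,0.2814,0.9025
D11,Quartic,0.3753,0.2815,0.9026
D11,Tricube,0.3756,0.2818,0.9024
D12,KNN,3051.2,2105.2,0.8507
D12,R-KNN,2983.6,1960.6,0.8810
D12,Gaussian,2961.1,1949.2,0.8824
D12,Epanechnikov,2919.6,1928.6,0.8848
D12,Uniform,2983.6,1960.6,0.8810
D12,Triangular,2879.4,1907.3,0.8871
D12,Quartic,2871.2,1904.3,0.8872
D12,Tricube,2877.5,1907.5,0.8869
D13,KNN,730.86,486.82,0.5993
D13,R-KNN,710.57,475.59,0.6254
D13,Gaussian,710.20,475.36,0.6255
D13,Epanechnikov,710.71,475.52,0.6247
D13,Uniform,710.57,475.55,0.6254
D13,Triangular,707.66,473.38,0.6272
D13,Quartic,710.54,475.21,0.6243
D13,Tricube,712.53,476.36,0.6224
D14,KNN,0.143249,0.0968667,0.62008
D14,R-KNN,0.141207,0.0969202,0.64373
D14,Gaussian,0.141195,0.0969090,0.64377
D14,Epanechnikov,0.141183,0.0968933,0.64380
D14,Uniform,0.141207,0.0969201,0.64373
D14,Triangular,0.141162,0.0968674,0.64385
D14,Quartic,0.141160,0.0968671,0.64387
D14,Tricube,0.141171,0.0968790,0.64385
D15,KNN,0.027170,0.021513,0.189703
D15,R-KNN,0.026824,0.021045,0.343268
D15,Gaussian,0.026820,0.021042,0.343363
D15,Epanechnikov,0.026806,0.021032,0.343543
D15,Uniform,0.026822,0.021044,0.343268
D15,Triangular,0.026802,0.021029,0.343651
D15,Quartic,0.026790,0.021020,0.343954
D15,Tricube,0.026784,0.021016,0.344055
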