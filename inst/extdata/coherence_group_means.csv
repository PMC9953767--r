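region,age_group,hemisphere,band,mean,sem
H,<20,left,alpha,0.1871,0.0079
H,<20,left,delta,0.1792,0.0068
H,<20,left,theta,0.1690,0.0124
H,<20,left,beta,0.1135,0.0072
H,<20,right,alpha,0.2020,0.0058
H,<20,right,delta,0.1745,0.0061
H,<20,right,theta,0.1692,0.0131
H,<20,right,beta,0.1261,0.0062
H,20-50,left,delta,0.2062,0.0180
H,20-50,left,theta,0.1668,0.0133
H,20-50,left,alpha,0.1376,0.0185
H,20-50,left,beta,0.1041,0.0050
H,20-50,right,delta,0.201,0.0156
H,20-50,right,theta,0.169,0.0185
H,20-50,right,alpha,0.145,0.0108
H,20-50,right,beta,0.104,0.0059
H,>50,left,alpha,0.2004,0.0230
H,>50,left,delta,0.1803,0.0067
H,>50,left,theta,0.1734,0.0124
H,>50,left,beta,0.1217,0.0174
H,>50,right,alpha,0.2232,0.0300
H,>50,right,delta,0.1890,0.0103
H,>50,right,theta,0.1854,0.0143
H,>50,right,beta,0.1351,0.0189
F,<20,left,delta,0.2711,0.0370
F,<20,left,theta,0.2276,0.0340
F,<20,left,alpha,0.1863,0.0271
F,<20,left,beta,0.1630,0.0243
F,<20,right,delta,0.2878,0.0185
F,<20,right,theta,0.2328,0.0173
F,<20,right,alpha,0.1716,0.0115
F,<20,right,beta,0.1581,0.0108
F,20-50,left,delta,0.2654,0.0327
F,20-50,left,theta,0.2100,0.0212
F,20-50,left,alpha,0.1722,0.0231
F,20-50,left,beta,0.1348,0.0162
F,20-50,right,delta,0.2486,0.0182
F,20-50,right,theta,0.205,0.0168
F,20-50,right,alpha,0.1646,0.016
F,20-50,right,beta,0.1283,0.0169
F,>50,left,delta,0.294,0.0216
F,>50,left,theta,0.2366,0.0198
F,>50,left,alpha,0.1679,0.0118
F,>50,left,beta,0.1575,0.0117
F,>50,right,delta,0.2544,0.0348
F,>50,right,theta,0.1986,0.0246
F,>50,right,alpha,0.1706,0.0344
F,>50,right,beta,0.1532,0.0240
PO,<20,left,alpha,0.2880,0.0412
PO,<20,left,theta,0.2331,0.0301
PO,<20,left,beta,0.1953,0.0348
PO,<20,left,delta,0.1910,0.018
PO,<20,right,alpha,0.1948,0.0187
PO,<20,right,theta,0.1738,0.0135
PO,<20,right,delta,0.1697,0.0098
PO,<20,right,beta,0.1314,0.0131
PO,20-50,left,alpha,0.2020,0.0595
PO,20-50,left,theta,0.1760,0.0378
PO,20-50,left,delta,0.1534,0.0167
PO,20-50,left,beta,0.1204,0.0446
PO,20-50,right,alpha,0.2883,0.0411
PO,20-50,right,theta,0.2266,0.0309
PO,20-50,right,beta,0.2026,0.0321
PO,20-50,right,delta,0.1827,0.0235
PO,>50,left,alpha,0.2041,0.0204
PO,>50,left,theta,0.1821,0.0152
PO,>50,left,delta,0.1731,0.0132
PO,>50,left,beta,0.1442,0.0166
PO,>50,right,alpha,0.2658,0.0672
PO,>50,right,theta,0.2376,0.0472
PO,>50,right,delta,0.1856,0.0201
PO,>50,right,beta,0.1376,0.0507
T,<20,left,alpha,0.2140,0.039
T,<20,left,delta,0.1686,0.0102
T,<20,left,theta,0.154,0.0218
T,<20,left,beta,0.0976,0.0179
T,<20,right,delta,0.2238,0.0194
T,<20,right,alpha,0.1940,0.0227
T,<20,right,theta,0.1907,0.0180
T,<20,right,beta,0.1265,0.0178
T,20-50,left,alpha,0.2596,0.0588
T,20-50,left,theta,0.2110,0.0367
T,20-50,left,delta,0.1870,0.0132
T,20-50,left,beta,0.1492,0.0402
T,20-50,right,alpha,0.3120,0.0478
T,20-50,right,theta,0.2110,0.0423
T,20-50,right,beta,0.1924,0.0646
T,20-50,right,delta,0.1647,0.0084
T,>50,left,delta,0.2236,0.0244
T,>50,left,alpha,0.2117,0.0237
T,>50,left,theta,0.2001,0.0235
T,>50,left,beta,0.131,0.0185
T,>50,right,alpha,0.3330,0.1010
T,>50,right,theta,0.2644,0.0799
T,>50,right,delta,0.2314,0.0350
T,>50,right,beta,0.172,0.0668
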