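energy_keV,mu_total_per_cm,mu_pe_per_cm
8.000,147.926,145.733
8.500,124.181,122.099
9.000,105.223,103.243
9.500,89.8311,87.9464
10.000,77.3068,75.5099
10.500,67.0123,65.2964
11.000,58.473,56.8318
11.500,51.3305,49.7582
12.000,45.3108,43.8021
12.500,40.202,38.7519
13.000,35.8383,34.4423
13.500,32.0889,30.7429
14.000,28.8496,27.5498
14.500,26.0366,24.7796
15.000,23.5822,22.3649
15.500,21.4311,20.2507
16.000,19.5379,18.3919
16.500,17.8652,16.7512
17.000,16.3818,15.2977
17.500,15.0618,14.0057
18.000,13.8833,12.8533
18.500,12.8278,11.8225
19.000,11.8798,10.8975
19.500,11.0259,10.0654
20.000,10.2548,9.31468
20.500,9.55658,8.63582
21.000,8.92295,8.02045
21.500,8.34659,7.46137
22.000,7.82119,6.95232
22.500,7.34123,6.48787
23.000,6.90192,6.06328
23.500,6.49904,5.67439
24.000,6.12891,5.31755
24.500,5.78825,4.98956
25.000,5.4742,4.68757
25.500,5.18422,4.40909
26.000,4.91603,4.15188
26.500,4.66764,3.91397
27.000,4.43699,3.69334
27.500,4.22262,3.48855
28.000,4.02327,3.29838
28.500,3.83766,3.12156
29.000,3.66463,2.95695
29.500,3.50311,2.80351
30.000,3.35218,2.66033
30.500,3.21097,2.52657
31.000,3.07872,2.40148
31.500,2.95473,2.28436
32.000,2.83835,2.17461
32.500,2.72902,2.07165
33.000,2.6262,1.97497
33.500,2.52942,1.88411
34.000,2.43824,1.79864
34.500,2.35225,1.71816
35.000,2.2711,1.64233
35.500,2.19445,1.57081
36.000,2.12198,1.50331
36.500,2.05342,1.43955
37.000,1.9885,1.37928
37.500,1.92698,1.32226
38.000,1.86865,1.26828
38.500,1.81329,1.21714
39.000,1.76072,1.16867
39.500,1.71077,1.12268
40.000,1.66327,1.07903
40.500,1.61807,1.03756
41.000,1.57503,0.998156
41.500,1.53402,0.96068
42.000,1.49494,0.925018
42.500,1.45765,0.891065
43.000,1.42206,0.85872
43.500,1.38807,0.827889
44.000,1.3556,0.798487
44.500,1.32455,0.770432
45.000,1.29485,0.74365
45.500,1.26643,0.718068
46.000,1.23921,0.693622
46.500,1.21314,0.670251
47.000,1.18814,0.647895
47.500,1.16418,0.626502
48.000,1.14118,0.60602
48.500,1.11911,0.586403
49.000,1.09791,0.567605
49.500,1.07755,0.549585
50.000,1.05797,0.532303
50.500,1.03915,0.515722
51.000,1.02104,0.499809
51.500,1.00362,0.484528
52.000,0.986841,0.469851
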