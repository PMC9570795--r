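energy_keV,mu_total_per_cm,mu_pe_per_cm
8.000,1427.58,1410.1
8.500,1217.85,1201.27
9.000,1047.71,1031.94
9.500,907.925,892.903
10.000,792.236,777.901
10.500,695.677,681.974
11.000,614.419,601.3
11.500,545.597,533.016
12.000,486.89,474.809
12.500,436.488,424.871
13.000,392.961,381.777
13.500,355.162,344.384
14.000,322.169,311.772
14.500,293.233,283.194
15.000,267.742,258.04
15.500,245.191,235.809
16.000,225.164,216.085
16.500,207.312,198.52
17.000,191.34,182.823
17.500,177.009,168.752
18.000,164.107,156.099
18.500,152.462,144.692
19.000,141.921,134.379
19.500,132.356,125.031
20.000,123.651,116.534
20.500,115.712,108.795
21.000,108.458,101.731
21.500,101.811,95.2677
22.000,95.7134,89.3454
22.500,90.1079,83.9084
23.000,84.9428,78.905
23.500,80.1785,74.2959
24.000,75.7761,70.0425
24.500,71.7015,66.111
25.000,67.9243,62.4711
25.500,64.4174,59.0963
26.000,61.1568,55.9625
26.500,58.1209,53.0485
27.000,55.2727,50.3175
27.500,52.6044,47.7618
28.000,50.1126,45.3784
28.500,47.7828,43.1527
29.000,45.6017,41.0719
29.500,43.5575,39.1243
30.000,41.6395,37.2992
30.500,39.838,35.5871
31.000,38.1441,33.9794
31.500,36.5498,32.4681
32.000,35.0477,31.0461
32.500,33.6313,29.7067
33.000,32.2943,28.4442
33.168,31.8619,28.0362
33.172,177.247,173.422
33.500,172.773,168.995
34.000,166.248,162.539
34.500,160.056,156.414
35.000,154.188,150.61
35.500,148.625,145.109
36.000,143.33,139.875
36.500,138.289,134.892
37.000,133.486,130.145
37.500,128.907,125.621
38.000,124.539,121.305
38.500,120.369,117.186
39.000,116.387,113.253
39.500,112.582,109.496
40.000,108.943,105.904
40.500,105.463,102.468
41.000,102.132,99.1809
41.500,98.9426,96.0335
42.000,95.8868,93.0186
42.500,92.9579,90.1293
43.000,90.1492,87.3591
43.500,87.4512,84.6984
44.000,84.861,82.1444
44.500,82.374,79.6927
45.000,79.9853,77.3382
45.500,77.69,75.0761
46.000,75.4834,72.9019
46.500,73.3614,70.8113
47.000,71.3198,68.8003
47.500,69.3549,66.8651
48.000,67.463,65.0022
48.500,65.6407,63.2081
49.000,63.8849,61.4798
49.500,62.1925,59.8141
50.000,60.5607,58.2084
50.500,58.9868,56.6598
51.000,57.4681,55.1658
51.500,56.0022,53.7241
52.000,54.587,52.3324
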