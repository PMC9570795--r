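energy_keV,mu_total_per_cm
8.000,3235.18
8.370,2865.56
8.390,3286.59
8.500,3181.39
9.000,2754.8
9.500,2398.21
10.000,2101.84
10.500,1853.16
11.000,1642.8
11.500,1463.73
12.000,1310.3
12.500,1178.02
13.000,1063.33
13.500,963.361
14.000,875.803
14.500,798.761
15.000,730.581
15.500,670.121
16.000,616.281
16.500,568.142
17.000,524.989
17.500,486.188
18.000,451.217
18.500,419.608
19.000,390.962
19.500,364.934
20.000,341.228
20.500,319.588
21.000,299.789
21.500,281.638
22.000,264.963
22.500,249.616
23.000,235.465
23.500,222.394
24.000,210.301
24.500,199.093
25.000,188.691
25.500,179.022
26.000,170.022
26.500,161.633
27.000,153.792
27.500,146.46
28.000,139.603
28.500,133.181
29.000,127.161
29.500,121.512
30.000,116.203
30.500,111.211
31.000,106.51
31.500,102.079
32.000,97.8929
32.500,93.9416
33.000,90.2082
33.500,86.6778
34.000,83.3365
34.500,80.1698
35.000,77.1634
35.500,74.3118
36.000,71.605
36.500,69.0293
37.000,66.575
37.500,64.241
38.000,62.0199
38.500,59.9047
39.000,57.8893
39.500,55.9676
40.000,54.1343
40.500,52.3841
41.000,50.7124
41.500,49.1148
42.000,47.5871
42.500,46.1255
43.000,44.7263
43.500,43.3864
44.000,42.1024
44.500,40.8714
45.000,39.6908
45.500,38.5578
46.000,37.4702
46.500,36.4256
47.000,35.4218
47.500,34.4569
48.000,33.529
48.500,32.6362
49.000,31.777
49.500,30.9497
50.000,30.1528
50.235,29.7883
50.245,146.351
50.500,144.506
51.000,140.976
51.500,137.559
52.000,134.249
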