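energy_keV,mu_total_per_cm
8.000,9.98878
8.500,8.34344
9.000,7.04486
9.500,6.00613
10.000,5.16693
10.500,4.4788
11.000,3.9124
11.500,3.44206
12.000,3.04833
12.500,2.71626
13.000,2.43427
13.500,2.19325
14.000,1.98605
14.500,1.80694
15.000,1.6513
15.500,1.51541
16.000,1.39623
16.500,1.29126
17.000,1.19843
17.500,1.11603
18.000,1.04264
18.500,0.977032
19.000,0.918209
19.500,0.865304
20.000,0.817586
20.500,0.774427
21.000,0.735291
21.500,0.699713
22.000,0.667293
22.500,0.637684
23.000,0.610582
23.500,0.585723
24.000,0.562877
24.500,0.54184
25.000,0.522433
25.500,0.504497
26.000,0.487894
26.500,0.472498
27.000,0.458126
27.500,0.444721
28.000,0.432244
28.500,0.420613
29.000,0.409756
29.500,0.399607
30.000,0.390107
30.500,0.381204
31.000,0.372849
31.500,0.364999
32.000,0.357614
32.500,0.35066
33.000,0.344103
33.500,0.337914
34.000,0.332067
34.500,0.326536
35.000,0.3213
35.500,0.316338
36.000,0.31163
36.500,0.30716
37.000,0.302912
37.500,0.298871
38.000,0.295024
38.500,0.291358
39.000,0.287862
39.500,0.284525
40.000,0.281337
40.500,0.27829
41.000,0.275375
41.500,0.272584
42.000,0.269909
42.500,0.267345
43.000,0.264885
43.500,0.262523
44.000,0.260253
44.500,0.258071
45.000,0.255972
45.500,0.253951
46.000,0.252004
46.500,0.250128
47.000,0.248318
47.500,0.246572
48.000,0.244886
48.500,0.243257
49.000,0.241683
49.500,0.24016
50.000,0.238686
50.500,0.23726
51.000,0.235878
51.500,0.234539
52.000,0.23324
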