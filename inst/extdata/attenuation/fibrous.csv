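energy_keV,mu_total_per_cm
8.000,9.23886
8.500,7.71673
9.000,6.51585
9.500,5.5556
10.000,4.7801
10.500,4.14434
11.000,3.62121
11.500,3.1869
12.000,2.82342
12.500,2.51692
13.000,2.25669
13.500,2.03432
14.000,1.84317
14.500,1.67796
15.000,1.53441
15.500,1.4091
16.000,1.2992
16.500,1.20241
17.000,1.11682
17.500,1.04085
18.000,0.973184
18.500,0.912704
19.000,0.858474
19.500,0.809701
20.000,0.765708
20.500,0.725919
21.000,0.689837
21.500,0.657034
22.000,0.627142
22.500,0.599839
23.000,0.574848
23.500,0.551923
24.000,0.530853
24.500,0.511449
25.000,0.493547
25.500,0.477002
26.000,0.461683
26.500,0.447476
27.000,0.434212
27.500,0.421837
28.000,0.410317
28.500,0.399578
29.000,0.389551
29.500,0.380177
30.000,0.371402
30.500,0.363176
31.000,0.355456
31.500,0.348201
32.000,0.341375
32.500,0.334946
33.000,0.328883
33.500,0.323159
34.000,0.31775
34.500,0.312633
35.000,0.307787
35.500,0.303194
36.000,0.298835
36.500,0.294695
37.000,0.29076
37.500,0.287016
38.000,0.283451
38.500,0.280052
39.000,0.27681
39.500,0.273715
40.000,0.270757
40.500,0.267929
41.000,0.265223
41.500,0.262631
42.000,0.260147
42.500,0.257764
43.000,0.255477
43.500,0.253281
44.000,0.25117
44.500,0.24914
45.000,0.247186
45.500,0.245304
46.000,0.243491
46.500,0.241743
47.000,0.240057
47.500,0.238429
48.000,0.236856
48.500,0.235336
49.000,0.233866
49.500,0.232445
50.000,0.231068
50.500,0.229735
51.000,0.228443
51.500,0.227191
52.000,0.225976
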