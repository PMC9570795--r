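energy_keV,mu_total_per_cm
8.000,5.76471
8.500,4.82295
9.000,4.08076
9.500,3.48704
10.000,3.00844
10.500,2.61733
11.000,2.29572
11.500,2.02888
12.000,1.80566
12.500,1.61749
13.000,1.45776
13.500,1.32129
14.000,1.20398
14.500,1.10259
15.000,1.01448
15.500,0.937549
16.000,0.870061
16.500,0.810601
17.000,0.758003
17.500,0.711294
18.000,0.669665
18.500,0.632436
19.000,0.599034
19.500,0.568973
20.000,0.541839
20.500,0.517279
21.000,0.494989
21.500,0.474709
22.000,0.456213
22.500,0.439304
23.000,0.423812
23.500,0.409588
24.000,0.396501
24.500,0.384437
25.000,0.373296
25.500,0.362986
26.000,0.353431
26.500,0.344559
27.000,0.336266
27.500,0.328518
28.000,0.321297
28.500,0.314557
29.000,0.308255
29.500,0.302354
30.000,0.296823
30.500,0.291629
31.000,0.286747
31.500,0.282152
32.000,0.277822
32.500,0.273735
33.000,0.269875
33.500,0.266224
34.000,0.262768
34.500,0.259491
35.000,0.256382
35.500,0.253429
36.000,0.250621
36.500,0.247949
37.000,0.245403
37.500,0.242975
38.000,0.240658
38.500,0.238444
39.000,0.236327
39.500,0.234301
40.000,0.23236
40.500,0.2305
41.000,0.228716
41.500,0.227002
42.000,0.225355
42.500,0.223772
43.000,0.222248
43.500,0.22078
44.000,0.219366
44.500,0.218002
45.000,0.216686
45.500,0.215414
46.000,0.214186
46.500,0.212998
47.000,0.211848
47.500,0.210735
48.000,0.209657
48.500,0.208612
49.000,0.207598
49.500,0.206615
50.000,0.205659
50.500,0.204732
51.000,0.20383
51.500,0.202952
52.000,0.202099
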