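energy_keV,mu_total_per_cm
8.000,132.999
8.500,111.506
9.000,94.3756
9.500,80.4955
10.000,69.2145
10.500,59.9524
11.000,52.2777
11.500,45.8651
12.000,40.4659
12.500,35.8878
13.000,31.981
13.500,28.627
14.000,25.7315
14.500,23.2191
15.000,21.0285
15.500,19.1099
16.000,17.4225
16.500,15.9325
17.000,14.6119
17.500,13.4374
18.000,12.3894
18.500,11.4513
19.000,10.609
19.500,9.85078
20.000,9.1663
20.500,8.54686
21.000,7.98491
21.500,7.47395
22.000,7.00834
22.500,6.58315
23.000,6.19411
23.500,5.83745
24.000,5.50988
24.500,5.20849
25.000,4.93073
25.500,4.67432
26.000,4.43726
26.500,4.21775
27.000,4.01409
27.500,3.82494
28.000,3.64908
28.500,3.48537
29.000,3.33277
29.500,3.19035
30.000,3.05728
30.500,2.93281
31.000,2.81624
31.500,2.70696
32.000,2.60441
32.500,2.50808
33.000,2.41749
33.500,2.33223
34.000,2.2519
34.500,2.17616
35.000,2.10468
35.500,2.03716
36.000,1.97333
36.500,1.91294
37.000,1.85576
37.500,1.80157
38.000,1.75019
38.500,1.70143
39.000,1.65512
39.500,1.61111
40.000,1.56927
40.500,1.52944
41.000,1.49152
41.500,1.45539
42.000,1.42094
42.500,1.38808
43.000,1.35671
43.500,1.32674
44.000,1.29811
44.500,1.27073
45.000,1.24454
45.500,1.21947
46.000,1.19545
46.500,1.17245
47.000,1.15039
47.500,1.12923
48.000,1.10893
48.500,1.08943
49.000,1.07071
49.500,1.05271
50.000,1.03542
50.500,1.01878
51.000,1.00277
51.500,0.987354
52.000,0.972511
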