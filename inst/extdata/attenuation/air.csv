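energy_keV,mu_total_per_cm,mu_en_rho_cm2_g
8.000,0.0115703,9.15676
8.500,0.00967016,7.59887
9.000,0.00816861,6.36951
9.500,0.00696363,5.38439
10.000,0.00599044,4.59004
10.500,0.00519484,3.94175
11.000,0.00453936,3.4086
11.500,0.00399451,2.96631
12.000,0.00353795,2.59644
12.500,0.00315251,2.28487
13.000,0.00282488,2.02065
13.500,0.00254461,1.79517
14.000,0.00230339,1.6016
14.500,0.00209456,1.43448
15.000,0.00191299,1.28957
15.500,0.00175435,1.16335
16.000,0.00161513,1.05292
16.500,0.00149243,0.955914
17.000,0.00138386,0.870366
17.500,0.00128743,0.794653
18.000,0.00120149,0.727415
18.500,0.00112463,0.667511
19.000,0.00105568,0.613978
19.500,0.000993631,0.566002
20.000,0.000937641,0.522887
20.500,0.000886979,0.48404
21.000,0.000841017,0.448953
21.500,0.000799218,0.417187
22.000,0.000761113,0.388363
22.500,0.000726298,0.362154
23.000,0.00069442,0.338272
23.500,0.000665171,0.31647
24.000,0.000638281,0.296528
24.500,0.000613511,0.278256
25.000,0.000590654,0.261486
25.500,0.000569524,0.246067
26.000,0.000549957,0.23187
26.500,0.000531808,0.218778
27.000,0.000514878,0.20663
27.500,0.00049909,0.195364
28.000,0.000484389,0.184939
28.500,0.000470681,0.17528
29.000,0.000457879,0.166319
29.500,0.000445907,0.157994
30.000,0.000434698,0.150252
30.500,0.000424189,0.143044
31.000,0.000414324,0.136326
31.500,0.000405052,0.130057
32.000,0.000396328,0.124201
32.500,0.000388109,0.118727
33.000,0.000380359,0.113603
33.500,0.000373042,0.108804
34.000,0.000366128,0.104305
34.500,0.000359587,0.100083
35.000,0.000353393,0.0961176
35.500,0.000347523,0.0923907
36.000,0.000341954,0.088885
36.500,0.000336666,0.0855849
37.000,0.000331642,0.0824761
37.500,0.000326862,0.0795453
38.000,0.000322313,0.0767805
38.500,0.00031798,0.0741705
39.000,0.000313848,0.071705
39.500,0.000309907,0.0693747
40.000,0.000306145,0.0671707
40.500,0.00030255,0.065085
41.000,0.000299114,0.06311
41.500,0.000295828,0.0612389
42.000,0.000292682,0.0594652
42.500,0.00028967,0.0577831
43.000,0.000286784,0.0561869
43.500,0.000284018,0.0546715
44.000,0.000281365,0.0532321
44.500,0.000278819,0.0518643
45.000,0.000276375,0.050564
45.500,0.000274029,0.0493273
46.000,0.000271774,0.0481505
46.500,0.000269608,0.0470303
47.000,0.000267526,0.0459635
47.500,0.000265524,0.0449473
48.000,0.000263598,0.0439788
48.500,0.000261746,0.0430554
49.000,0.000259964,0.0421748
49.500,0.000258249,0.0413347
50.000,0.000256599,0.0405329
50.500,0.00025501,0.0397675
51.000,0.000253482,0.0390365
51.500,0.00025201,0.0383382
52.000,0.000250594,0.037671
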