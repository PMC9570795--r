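energy_keV,k_fraction
33.180,0.866324
33.250,0.866385
33.500,0.866601
34.000,0.867024
34.500,0.867436
35.000,0.867847
35.500,0.868260
36.000,0.868659
36.500,0.869045
37.000,0.869420
37.500,0.869782
38.000,0.870133
38.500,0.870473
39.000,0.870802
39.500,0.871121
40.000,0.871431
40.500,0.871730
41.000,0.872021
41.500,0.872303
42.000,0.872576
42.500,0.872841
43.000,0.873098
43.500,0.873342
44.000,0.873577
44.500,0.873805
45.000,0.874027
45.500,0.874242
46.000,0.874452
46.500,0.874655
47.000,0.874852
47.500,0.875044
48.000,0.875231
48.500,0.875412
49.000,0.875588
49.500,0.875758
50.000,0.875924
50.500,0.876086
51.000,0.876242
51.500,0.876395
52.000,0.876542
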