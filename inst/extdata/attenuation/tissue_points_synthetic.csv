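material,energy_keV,mu_per_cm
fat,14.00,1.20398
fat,16.00,0.870061
fat,18.00,0.669665
fat,20.00,0.541839
fat,22.00,0.456213
fat,24.00,0.396501
fat,26.00,0.353431
fat,28.00,0.321297
fat,30.00,0.296823
fat,32.00,0.277822
fat,34.00,0.262768
fibrous,14.00,1.84317
fibrous,16.00,1.2992
fibrous,18.00,0.973184
fibrous,20.00,0.765708
fibrous,22.00,0.627142
fibrous,24.00,0.530853
fibrous,26.00,0.461683
fibrous,28.00,0.410317
fibrous,30.00,0.371402
fibrous,32.00,0.341375
fibrous,34.00,0.31775
tumor,14.00,1.98605
tumor,16.00,1.39623
tumor,18.00,1.04264
tumor,20.00,0.817586
tumor,22.00,0.667293
tumor,24.00,0.562877
tumor,26.00,0.487894
tumor,28.00,0.432244
tumor,30.00,0.390107
tumor,32.00,0.357614
tumor,34.00,0.332067
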