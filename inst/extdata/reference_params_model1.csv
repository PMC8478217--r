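name,value,lower_bound,upper_bound
k_f1,0.203775206245177,0.000203775206245177,203.775206245177
Km_1,42.8051936180182,0.0428051936180182,42805.1936180182
k_r1,0.258024952228819,0.000258024952228819,258.024952228819
k_f1b,1.0629184793681,0.0010629184793681,1062.9184793681
Km_1b,31.7832195898239,0.0317832195898239,31783.2195898239
k_f2,1.18376081225253,0.00118376081225253,1183.76081225253
Km_2,47.5507833658612,0.0475507833658612,47550.7833658612
k_r2,0.260622658543341,0.000260622658543341,260.622658543341
k_f2b,1.07398322919725,0.00107398322919725,1073.98322919725
Km_2b,36.0774063591676,0.0360774063591676,36077.4063591676
k_r2b,0.0442209937677046,4.42209937677046e-05,44.2209937677046
k_f3,0.574336360004478,0.000574336360004478,574.336360004478
Km_3,45.7148017452534,0.0457148017452534,45714.8017452534
k_r3,0.29932073592914,0.00029932073592914,299.32073592914
k_f4,10.2221090642192,0.0102221090642192,10222.1090642192
Km_4,45.571268775614,0.045571268775614,45571.268775614
k_r4,0.84956364152546,0.00084956364152546,849.56364152546
Km_4b,37.4511443958155,0.0374511443958155,37451.1443958155
k_f5,0.0444298248090693,4.44298248090693e-05,44.4298248090693
k_r5,0.160296331514012,0.000160296331514012,160.296331514012
k_f6,0.0181420831970244,1.81420831970244e-05,18.1420831970244
k_r6,0.182664447758778,0.000182664447758778,182.664447758778
k_f7,0.522597172890916,0.000522597172890916,522.597172890916
Km_7,42.7671416482629,0.0427671416482629,42767.1416482629
k_f7b,0.00569316494610862,5.69316494610862e-06,5.69316494610862
k_r7,0.243557619657762,0.000243557619657762,243.557619657762
k_f8,0.419888112617963,0.000419888112617963,419.888112617963
Km_8,35.7460444442155,0.0357460444442155,35746.0444442155
k_r8,0.522260878202339,0.000522260878202339,522.260878202339
k_f9,0.531485042094329,0.000531485042094329,531.485042094329
Km_9,50.1079729876,0.0501079729876,50107.9729876
k_r9,0.320204604413207,0.000320204604413207,320.204604413207
k_f10a,0.611867525579411,0.000611867525579411,611.867525579411
Km_10a,32.6402828200139,0.0326402828200139,32640.2828200139
k_f10b,0.0494487499829777,4.94487499829777e-05,49.4487499829777
Km_10b,42.944355400903,0.042944355400903,42944.355400903
k_r10a,0.254077663343139,0.000254077663343139,254.077663343139
k_r10b,0.319711854928752,0.000319711854928752,319.711854928752
k_f11a,10.9346997522662,0.0109346997522662,10934.6997522662
k_i1,0.21931469981963,0.00021931469981963,219.31469981963
k_r11,0.974524596275457,0.000974524596275457,974.524596275457
k_f11b,1.61090966558107,0.00161090966558107,1610.90966558107
Km_11b,41.0499228387958,0.0410499228387958,41049.9228387957
k_r11b,0.53585933378871,0.00053585933378871,535.85933378871
k_f12a,0.00947278032560527,9.47278032560527e-06,9.47278032560527
Km_12a,40.859628938,0.040859628938,40859.628938
k_f12b,6.18623794896504,0.00618623794896504,6186.23794896504
Km_12b,24.5982597959586,0.0245982597959586,24598.2597959586
k_r12,0.120746878466169,0.000120746878466169,120.746878466169
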