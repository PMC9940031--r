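source_table,model,dataset,extractor,normalized,n_real,fid_rr,fid_rs,rfid_printed
models,1,INbreast,imagenet,,1000,33.61,67.60,0.497
models,2,OPTIMAM,imagenet,,1000,28.85,80.51,0.358
models,3,BCDR,imagenet,,74,65.94,150.16,0.439
models,4,BCDR,imagenet,,199,68.22,161.17,0.423
models,5,BCDR,imagenet,,199,68.22,180.04,0.379
models,6,BCDR,imagenet,,199,68.22,221.30,0.308
models,7,BRATS2018,imagenet,,1000,30.73,140.02,0.219
models,8,CBIS-DDSM,imagenet,,379,37.56,137.75,0.272
models,9,HyperKvasir,imagenet,,1000,43.31,225.85,0.192
models,10,HyperKvasir,imagenet,,1000,43.31,63.99,0.677
models,11,HyperKvasir,imagenet,,1000,43.31,171.15,0.253
models,12,BCDR,imagenet,,199,68.22,205.29,0.332
models,13,OPTIMAM,imagenet,,358,65.75,101.09,0.650
models,14,OPTIMAM,imagenet,,350,41.61,73.77,0.564
models,15,CSAW,imagenet,,192,74.96,162.67,0.461
models,16,CSAW,imagenet,,202,42.68,98.38,0.434
models,17,NODE21,imagenet,,1476,24.34,126.78,0.192
models,18,NODE21,imagenet,,1476,24.34,211.47,0.115
models,19,ChestX-ray14,imagenet,,1000,28.74,96.74,0.297
models,20,ChestX-ray14,imagenet,,1000,28.33,52.17,0.543
models,21,CrossMoDA,imagenet,,1000,24.41,59.49,0.410
normalization,1,INbreast,imagenet,yes,1000,33.61,67.60,0.497
normalization,1,INbreast,radimagenet,yes,1000,0.25,1.27,0.197
normalization,1,INbreast,imagenet,no,1000,28.59,66.76,0.428
normalization,1,INbreast,radimagenet,no,1000,0.29,1.15,0.252
normalization,2,OPTIMAM,imagenet,yes,1000,28.85,80.51,0.358
normalization,2,OPTIMAM,radimagenet,yes,1000,0.22,6.19,0.036
normalization,2,OPTIMAM,imagenet,no,1000,28.75,77.95,0.369
normalization,2,OPTIMAM,radimagenet,no,1000,0.33,4.11,0.080
normalization,3,BCDR,imagenet,yes,74,65.94,150.16,0.439
normalization,3,BCDR,radimagenet,yes,74,0.80,3.00,0.265
normalization,3,BCDR,imagenet,no,74,66.25,149.33,0.444
normalization,3,BCDR,radimagenet,no,74,0.80,3.10,0.259
normalization,5,BCDR,imagenet,yes,199,68.22,180.04,0.379
normalization,5,BCDR,radimagenet,yes,199,0.99,1.67,0.593
normalization,5,BCDR,imagenet,no,199,64.45,174.38,0.370
normalization,5,BCDR,radimagenet,no,199,0.87,4.04,0.215
normalization,6,BCDR,imagenet,yes,199,68.22,221.30,0.308
normalization,6,BCDR,radimagenet,yes,199,0.99,1.80,0.550
normalization,6,BCDR,imagenet,no,199,64.45,206.57,0.312
normalization,6,BCDR,radimagenet,no,199,0.87,2.95,0.295
normalization,7,BRATS2018,imagenet,yes,1000,30.73,140.02,0.219
normalization,7,BRATS2018,radimagenet,yes,1000,0.07,5.31,0.012
normalization,7,BRATS2018,imagenet,no,1000,30.73,144.00,0.215
normalization,7,BRATS2018,radimagenet,no,1000,0.07,6.53,0.010
normalization,8,CBIS-DDSM,imagenet,yes,379,37.56,137.75,0.272
normalization,8,CBIS-DDSM,radimagenet,yes,379,0.46,3.05,0.151
normalization,8,CBIS-DDSM,imagenet,no,379,32.06,91.09,0.352
normalization,8,CBIS-DDSM,radimagenet,no,379,0.36,6.58,0.055
normalization,10,HyperKvasir,imagenet,yes,1000,43.31,63.99,0.677
normalization,10,HyperKvasir,radimagenet,yes,1000,0.11,7.32,0.015
normalization,10,HyperKvasir,imagenet,no,1000,43.31,64.01,0.677
normalization,10,HyperKvasir,radimagenet,no,1000,0.11,7.33,0.015
normalization,12,BCDR,imagenet,yes,199,68.22,205.29,0.332
normalization,12,BCDR,radimagenet,yes,199,0.99,5.69,0.080
normalization,12,BCDR,imagenet,no,199,64.45,199.50,0.323
normalization,12,BCDR,radimagenet,no,199,0.87,4.25,0.205
normalization,13,OPTIMAM,imagenet,yes,358,65.75,101.01,0.650
normalization,13,OPTIMAM,radimagenet,yes,358,0.17,1.14,0.153
normalization,13,OPTIMAM,imagenet,no,358,65.83,101.15,0.651
normalization,13,OPTIMAM,radimagenet,no,358,0.18,1.10,0.163
normalization,14,OPTIMAM,imagenet,yes,350,41.61,73.77,0.564
normalization,14,OPTIMAM,radimagenet,yes,350,0.16,0.83,0.190
normalization,14,OPTIMAM,imagenet,no,350,41.71,74.03,0.563
normalization,14,OPTIMAM,radimagenet,no,350,0.15,0.81,0.184
normalization,15,CSAW,imagenet,yes,192,74.96,162.67,0.461
normalization,15,CSAW,radimagenet,yes,192,0.31,4.07,0.076
normalization,15,CSAW,imagenet,no,192,73.62,165.53,0.445
normalization,15,CSAW,radimagenet,no,192,0.19,3.71,0.051
normalization,16,CSAW,imagenet,yes,202,42.68,98.38,0.439
normalization,16,CSAW,radimagenet,yes,202,0.38,2.71,0.142
normalization,16,CSAW,imagenet,no,202,42.50,99.81,0.426
normalization,16,CSAW,radimagenet,no,202,0.22,2.82,0.077
normalization,19,ChestX-ray14,imagenet,yes,1000,28.75,96.74,0.297
normalization,19,ChestX-ray14,radimagenet,yes,1000,0.19,0.77,0.243
normalization,19,ChestX-ray14,imagenet,no,1000,28.75,96.78,0.297
normalization,19,ChestX-ray14,radimagenet,no,1000,0.19,0.66,0.286
normalization,20,ChestX-ray14,imagenet,yes,1000,28.33,52.17,0.543
normalization,20,ChestX-ray14,radimagenet,yes,1000,0.20,2.83,0.071
normalization,20,ChestX-ray14,imagenet,no,1000,28.33,52.38,0.541
normalization,20,ChestX-ray14,radimagenet,no,1000,0.20,2.59,0.077
normalization,21,CrossMoDA,imagenet,yes,1000,24.41,59.49,0.410
normalization,21,CrossMoDA,radimagenet,yes,1000,0.02,1.45,0.014
normalization,21,CrossMoDA,imagenet,no,1000,24.41,60.11,0.406
normalization,21,CrossMoDA,radimagenet,no,1000,0.02,1.40,0.014
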