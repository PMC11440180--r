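wavelength_nm,free_nadh,bound_nadh
380,0.046265,0.138301
382,0.053372,0.15608
384,0.061319,0.175368
386,0.070162,0.196185
388,0.079961,0.218534
390,0.090769,0.242403
392,0.102639,0.267763
394,0.115617,0.294566
396,0.129745,0.322746
398,0.145058,0.352215
400,0.161585,0.382871
402,0.179346,0.414587
404,0.198349,0.447223
406,0.218597,0.480618
408,0.240077,0.514597
410,0.262769,0.54897
412,0.286639,0.583535
414,0.311639,0.618078
416,0.337711,0.652378
418,0.364783,0.686211
420,0.392771,0.719346
422,0.421579,0.751555
424,0.451099,0.782613
426,0.481212,0.8123
428,0.511789,0.840404
430,0.54269,0.866725
432,0.57377,0.891077
434,0.604874,0.913289
436,0.635845,0.933207
438,0.666519,0.9507
440,0.696731,0.965654
442,0.726316,0.977979
444,0.755107,0.987608
446,0.782944,0.994498
448,0.809667,0.998628
450,0.835124,1
452,0.85917,0.99864
454,0.881669,0.994595
456,0.902494,0.987933
458,0.92153,0.97874
460,0.938675,0.967122
462,0.953838,0.9532
464,0.966944,0.937108
466,0.977932,0.918994
468,0.986755,0.899016
470,0.993383,0.877339
472,0.997798,0.854134
474,0.999999,0.829578
476,1,0.803847
478,0.997829,0.777121
480,0.993526,0.749574
482,0.987145,0.72138
484,0.978754,0.692708
486,0.968429,0.663719
488,0.956257,0.634569
490,0.942334,0.605405
492,0.926766,0.576363
494,0.909663,0.547573
496,0.89114,0.519153
498,0.871321,0.491208
500,0.850327,0.463836
502,0.828285,0.437123
504,0.805323,0.411142
506,0.781566,0.38596
508,0.757141,0.361628
510,0.732171,0.338193
512,0.706777,0.315688
514,0.681076,0.294138
516,0.65518,0.273563
518,0.629198,0.25397
520,0.603231,0.235363
522,0.577376,0.217738
524,0.551723,0.201084
526,0.526356,0.185387
528,0.50135,0.170627
530,0.476777,0.15678
532,0.452699,0.143819
534,0.429172,0.131716
536,0.406246,0.120437
538,0.383964,0.109949
540,0.362363,0.100216
542,0.341473,0.091204
544,0.321317,0.082874
546,0.301916,0.075192
548,0.283282,0.068119
550,0.265423,0.06162
552,0.248344,0.05566
554,0.232045,0.050204
556,0.21652,0.045218
558,0.201762,0.040669
560,0.18776,0.036528
562,0.1745,0.032762
564,0.161966,0.029345
566,0.150138,0.026249
568,0.138998,0.023448
570,0.128523,0.020919
572,0.118689,0.018638
574,0.109473,0.016584
576,0.100851,0.014738
578,0.092795,0.013081
580,0.085282,0.011596
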