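t_frac,w
0,0.94062
0.01,0.995437
0.02,1.054502
0.03,1.117078
0.04,1.1823
0.05,1.249191
0.06,1.316691
0.07,1.383678
0.08,1.448998
0.09,1.511494
0.1,1.570041
0.11,1.623568
0.12,1.671092
0.13,1.711744
0.14,1.744791
0.15,1.769656
0.16,1.785932
0.17,1.793396
0.18,1.792008
0.19,1.781919
0.2,1.763457
0.21,1.737122
0.22,1.703569
0.23,1.66359
0.24,1.618086
0.25,1.568047
0.26,1.514519
0.27,1.458581
0.28,1.401306
0.29,1.343743
0.3,1.286883
0.31,1.231635
0.32,1.178808
0.33,1.12909
0.34,1.083036
0.35,1.041059
0.36,1.003425
0.37,0.970256
0.38,0.941532
0.39,0.917104
0.4,0.896705
0.41,0.879967
0.42,0.866444
0.43,0.855629
0.44,0.846977
0.45,0.839931
0.46,0.833941
0.47,0.828486
0.48,0.823094
0.49,0.817355
0.5,0.810937
0.51,0.803594
0.52,0.795172
0.53,0.785609
0.54,0.774936
0.55,0.763267
0.56,0.750793
0.57,0.737769
0.58,0.724496
0.59,0.71131
0.6,0.69856
0.61,0.686594
0.62,0.675739
0.63,0.666287
0.64,0.658478
0.65,0.652491
0.66,0.648436
0.67,0.646342
0.68,0.646165
0.69,0.64778
0.7,0.650991
0.71,0.655538
0.72,0.66111
0.73,0.667359
0.74,0.673912
0.75,0.680396
0.76,0.68645
0.77,0.691746
0.78,0.696006
0.79,0.699021
0.8,0.700659
0.81,0.70088
0.82,0.699745
0.83,0.697417
0.84,0.69416
0.85,0.69034
0.86,0.686413
0.87,0.682913
0.88,0.680437
0.89,0.679627
0.9,0.681148
0.91,0.685665
0.92,0.693818
0.93,0.706198
0.94,0.723325
0.95,0.745622
0.96,0.7734
0.97,0.806834
0.98,0.845957
0.99,0.890647
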