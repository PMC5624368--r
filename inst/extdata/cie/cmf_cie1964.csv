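wavelength,xbar,ybar,zbar
380,2e-04,0,7e-04
390,0.0024,3e-04,0.0105
400,0.0191,0.002,0.086
410,0.0847,0.0088,0.3894
420,0.2045,0.0214,0.9725
430,0.3147,0.0387,1.5535
440,0.3837,0.0621,1.9673
450,0.3707,0.0895,1.9948
460,0.3023,0.1282,1.7454
470,0.1956,0.1852,1.3176
480,0.0805,0.2536,0.7721
490,0.0162,0.3391,0.4153
500,0.0038,0.4608,0.2185
510,0.0375,0.6067,0.112
520,0.1177,0.7618,0.0607
530,0.2365,0.8752,0.0305
540,0.3768,0.962,0.0137
550,0.5298,0.9918,0.004
560,0.7052,0.9973,0
570,0.8787,0.9556,0
580,1.0142,0.8689,0
590,1.1185,0.7774,0
600,1.124,0.6583,0
610,1.0305,0.528,0
620,0.8563,0.3981,0
630,0.6475,0.2835,0
640,0.4316,0.1798,0
650,0.2683,0.1076,0
660,0.1526,0.0603,0
670,0.0813,0.0318,0
680,0.0409,0.0159,0
690,0.0199,0.0077,0
700,0.0096,0.0037,0
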