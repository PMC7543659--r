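"x","rel_rms"
0,1.03
0.05,0.9906
0.1,0.952397
0.15,0.915386
0.2,0.879558
0.25,0.8449
0.3,0.811397
0.35,0.779033
0.4,0.747789
0.45,0.717643
0.5,0.688574
0.55,0.660559
0.6,0.633573
0.65,0.607592
0.7,0.582589
0.75,0.558541
0.8,0.535419
0.85,0.513197
0.9,0.49185
0.95,0.47135
1,0.451672
1.05,0.432789
1.1,0.414675
1.15,0.397305
1.2,0.380653
1.25,0.364695
1.3,0.349407
1.35,0.334764
1.4,0.320743
1.45,0.307322
1.5,0.294478
1.55,0.28219
1.6,0.270435
1.65,0.259195
1.7,0.248448
1.75,0.238176
1.8,0.228359
1.85,0.21898
1.9,0.21002
1.95,0.201463
2,0.193292
2.05,0.185492
2.1,0.178046
2.15,0.17094
2.2,0.164159
2.25,0.15769
2.3,0.15152
2.35,0.145636
2.4,0.140024
2.45,0.134674
2.5,0.129574
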