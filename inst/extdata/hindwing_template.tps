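LM=14
0.00 0.000
0.03 0.055
0.28 0.075
0.55 0.080
0.82 0.055
1.00 0.000
0.80 -0.070
0.55 -0.100
0.30 -0.105
0.10 -0.070
0.32 -0.015
0.58 -0.020
0.80 -0.020
0.16 0.010
ID=hindwing_template_synthetic
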