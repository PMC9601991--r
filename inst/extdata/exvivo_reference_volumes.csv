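specimen,water_displacement_ml,software_ml,percent
1,10,9.97,99.70
2,20,19.48,97.40
3,30,30.29,100.97
4,40,39.68,99.20
5,50,49.81,99.62
6,60,61.62,102.70
7,70,69.25,98.93
8,80,80.34,100.43
9,90,89.71,99.68
10,100,99.88,99.88
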