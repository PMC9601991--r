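group,n,or_mean,or_min,or_max,stage_I_n,stage_I_pct,stage_II_n,stage_II_pct,stage_III_n,stage_III_pct,volume_mean_cm3
intact,39,0.72,0.49,0.89,34,87.2,5,12.8,0,0,56.9
partial,75,0.54,0.26,0.79,31,41.3,38,50.7,6,8.0,43.6
full,35,0.40,0.11,0.71,1,2.9,16,45.7,18,51.4,31.1
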