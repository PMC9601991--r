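category,level,n
tendon_group,intact,39
tendon_group,partial,75
tendon_group,full,35
ellman_grade,I,45
ellman_grade,II,19
ellman_grade,III,11
patte_grade,1,19
patte_grade,2,10
patte_grade,3,6
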