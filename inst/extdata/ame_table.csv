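sex,age_min_years,age_max_years,ame
M,0,1,0.23
M,1,4,0.41
M,4,7,0.55
M,7,10,0.66
M,10,14,0.82
M,14,18,1.00
M,18,30,1.00
M,30,60,0.96
M,60,Inf,0.80
F,0,1,0.21
F,1,4,0.39
F,4,7,0.52
F,7,10,0.59
F,10,14,0.75
F,14,18,0.82
F,18,30,0.82
F,30,60,0.80
F,60,Inf,0.71
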