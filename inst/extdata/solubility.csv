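cas,name,endpoint,water_solubility,exp_lc50,n_models_incorrect,range_in_models
120-12-7,Anthracene,daphnia_48h,0.047,0.0356,4,
84-74-2,Dibutyl phthalate,daphnia_48h,11.2,0.5,4,1.4-3.7 (mean 3.52)
81-15-2,Musk xylene,fish_96h,0.15,0.2,3,2.9-47 (mean 9.87)
1763-23-1,Heptadecafluorooctanesulfonic acid,fish_96h,0.106,68,3,
732-26-3,"2,4,6-Tri-tert-butylphenol",fish_96h,0.063,0.048,3,0.06-0.1 (mean 0.07)
71-43-2,Benzene,fish_96h,1880,5.3,3,5.3-452 (mean 83)
117-81-7,Bis(2-ethylhexyl) phthalate,fish_96h,0.27,0.16,3,0.16-1106 (mean 573)
335-67-1,Pentadecafluorooctanoic acid,fish_96h,0.48,157,4,24.6-607 (mean 316)
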