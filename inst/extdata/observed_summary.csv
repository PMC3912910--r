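"bot10_lt0.77","bot10_0.77_0.81","bot10_0.81_0.85","bot10_0.85_0.89","bot10_0.89_0.93","bot10_0.93_0.97","bot10_ge0.97","bot20_lt0.77","bot20_0.77_0.81","bot20_0.81_0.85","bot20_0.85_0.89","bot20_0.89_0.93","bot20_0.93_0.97","bot20_ge0.97","bot30_lt0.77","bot30_0.77_0.81","bot30_0.81_0.85","bot30_0.85_0.89","bot30_0.89_0.93","bot30_0.93_0.97","bot30_ge0.97","bot40_lt0.77","bot40_0.77_0.81","bot40_0.81_0.85","bot40_0.85_0.89","bot40_0.89_0.93","bot40_0.93_0.97","bot40_ge0.97","bot50_lt0.77","bot50_0.77_0.81","bot50_0.81_0.85","bot50_0.85_0.89","bot50_0.89_0.93","bot50_0.93_0.97","bot50_ge0.97","slope_120","intercept_120","slope_240","intercept_240"
0,0,1,1,3,20,25,0,0,4,2,12,24,8,0,0,2,10,10,21,7,0,2,5,8,16,13,6,0,4,10,9,15,11,1,-0.7986,0.7585,-0.8873,0.8647
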