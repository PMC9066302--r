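key,strain_1,strain_2,mono_mean,co_mean,delta_od,alpha,r_squared
FG,pheA,glyA,0.4627,0.5417,0.079,0.39273,0.62
FH,pheA,hisB,0.77335,0.952,0.17865,0.69142,0.759
FI,pheA,ilvA,0.4064,0.5573,0.1509,0.351,0.666
FL,pheA,leuB,0.473,0.54,0.067,0.35761,0.749
FM,pheA,metA,0.466,0.56,0.094,0.39667,0.402
FT,pheA,thrC,0.49315,0.4858,-0.00735,0.44008,0.100
FW,pheA,trpC,0.52855,0.6215,0.09295,0.4694,0.750
FY,pheA,tyrA,0.4615,0.57,0.1085,0.46357,0.585
GH,glyA,hisB,0.4337,0.4263,-0.0074,0.29576,0.573
GI,glyA,ilvA,0.44935,0.5477,0.09835,0.36992,0.708
GL,glyA,leuB,0.4315,0.525,0.0935,0.35719,0.285
GM,glyA,metA,0.3605,0.471,0.1105,0.39148,0.290
GW,glyA,trpC,0.3821,0.4733,0.0912,0.35986,0.190
GY,glyA,tyrA,0.37035,0.6073,0.23695,0.30094,0.796
GT,glyA,thrC,0.36575,0.475,0.10925,0.29148,0.413
HI,hisB,ilvA,0.4185,0.477,0.0585,0.4071,0.190
HL,hisB,leuB,0.4274,0.573,0.1456,0.34599,0.748
HM,hisB,metA,0.47265,0.5682,0.09555,0.39923,0.681
HT,hisB,thrC,0.463,0.5415,0.0785,0.39782,0.494
HW,hisB,trpC,0.44285,0.5277,0.08485,0.39261,0.730
HY,hisB,tyrA,0.483,0.5495,0.0665,0.41851,0.414
IL,ilvA,leuB,0.43685,0.5525,0.11565,0.40002,0.886
IM,ilvA,metA,0.4559,0.5657,0.1098,0.43427,0.778
IT,ilvA,thrC,0.4489,0.4547,0.0058,0.46806,0.149
IW,ilvA,trpC,0.4905,0.5755,0.085,0.40843,0.764
IY,ilvA,tyrA,0.53095,0.587,0.05605,0.46823,0.276
LM,leuB,metA,0.44635,0.4697,0.02335,0.43427,0.422
LT,leuB,thrC,0.4596,0.4883,0.0287,0.46806,0.416
LW,leuB,trpC,0.46885,0.4828,0.01395,0.4099,0.416
LY,leuB,tyrA,0.57085,0.715,0.14415,0.45674,0.765
MT,metA,thrC,0.3871,0.4613,0.0742,0.32419,0.379
MW,metA,trpC,0.4221,0.4565,0.0344,0.31137,0.506
MY,metA,tyrA,0.365,0.5745,0.2095,0.28458,0.687
TW,thrC,trpC,0.4894,0.5862,0.0968,0.38874,0.778
TY,thrC,tyrA,0.45825,0.5655,0.10725,0.34843,0.802
WY,trpC,tyrA,0.47215,0.5945,0.12235,0.35519,0.035
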