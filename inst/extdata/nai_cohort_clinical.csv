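case,age,subtype_bl,subtype_surg,ki67_bl,ki67_surg,ki67_response,allred_bl,allred_surg,instability_index,n_clones,collision,manual_pattern
BRC10,57,LumB,LumA,0.492,0.035,sensitive,6,4,0.246,,FALSE,
BRC11,84,LumB,LumB,0.25,0.417,resistant,7,6,0.097,4,FALSE,
BRC14,86,LumB,LumA,0.442,0.012,sensitive,7,4,0,1,FALSE,
BRC15,83,LumB,LumA,0.238,0.01,sensitive,7,7,0.579,5,FALSE,
BRC17,63,LumB,LumA,0.32,0.019,sensitive,7,8,,,FALSE,complex_dynamic
BRC18,85,LumB,LumA,0.125,0,sensitive,8,7,,,FALSE,complex_dynamic
BRC20,61,LumB,LumB,0.456,0.349,resistant,4,6,0.856,,FALSE,
BRC21,73,LumA,Normal,0.058,0.019,sensitive,7,6,1,,TRUE,
BRC22,64,LumA,LumA,0.008,0,sensitive,6,7,0.533,,FALSE,
BRC24,51,LumB,LumB,0.152,0.155,resistant,7,7,0.403,,FALSE,
BRC26,71,LumB,LumA,0.101,0.07,sensitive,7,5,0.499,,FALSE,
BRC30,60,LumB,LumA,0.256,0.183,resistant,5,5,0.371,,FALSE,
BRC32,54,LumA,LumA,0.1,0,sensitive,7,6,0.450,,FALSE,
BRC37,56,LumB,LumB,0.76,0.308,resistant,6,4,0.359,,FALSE,
BRC38,78,LumB,Her2,0.162,0.471,resistant,8,2,1,,TRUE,
BRC39,79,LumB,LumA,0.356,0.124,resistant,6,5,0.841,,FALSE,
BRC40,66,LumA,LumA,0.076,0.008,sensitive,8,8,0.904,,FALSE,
BRC41,55,LumB,LumA,0.412,0.008,sensitive,8,6,0.535,,FALSE,
BRC42,74,LumB,LumA,0.081,0.022,sensitive,,8,0.341,,FALSE,
BRC48,66,LumA,LumA,,0.346,resistant,6,6,,,FALSE,complex_dynamic
BRC49,56,LumA,LumA,0.077,0.152,resistant,8,8,0.715,,FALSE,
BRC50,78,LumA,LumA,0.195,0.104,resistant,4,5,0.856,,FALSE,
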