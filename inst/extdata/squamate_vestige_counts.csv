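taxon,element,n,n_left_larger,n_right_larger,chi2,chi2_p,mean_pa,sd_pa,t,t_p
Agamodon anguliceps,pelvis,124,48,70,1.71,0.191,0.66,2.72,2.54,0.012
Bachia intermedia,pelvis,103,38,57,1.54,0.215,0.20,1.39,1.41,0.161
Indotyphlops braminus,pelvis,94,50,39,0.46,0.499,-0.43,3.50,-1.23,0.223
Ophisaurus spp.,pelvis,94,44,47,0.01,0.941,0.12,1.88,0.57,0.569
Chalcides sepsoides,pelvis,83,39,41,0.00,1.000,-0.18,0.82,-2.11,0.038
Teius teyou,pelvis,76,23,51,4.74,0.030,0.18,0.59,3.11,0.003
Bachia intermedia,femur,72,22,44,3.12,0.077,0.96,6.96,1.86,0.067
Chalcides sepsoides,femur,72,44,27,1.61,0.205,-0.64,1.62,-3.37,0.001
Teius teyou,femur,69,39,29,0.47,0.492,-0.28,2.85,-1.03,0.308
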