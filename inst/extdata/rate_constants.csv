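index_name,temperature_C,order,k,r2,t_half
overall_acceptability,5,0,0.0694,0.915,59.73
overall_acceptability,5,1,0.0089,0.909,NA
overall_acceptability,5,2,0.0011,0.902,NA
overall_acceptability,15,0,0.0815,0.988,50.86
overall_acceptability,15,1,0.0106,0.983,NA
overall_acceptability,15,2,0.0014,0.977,NA
overall_acceptability,25,0,0.1279,0.941,32.41
overall_acceptability,25,1,0.0175,0.920,NA
overall_acceptability,25,2,0.0024,0.897,NA
acidity,5,0,0.0212,0.959,14.50
acidity,5,1,0.0283,0.973,NA
acidity,5,2,0.0383,0.982,NA
acidity,15,0,0.0262,0.968,11.74
acidity,15,1,0.0339,0.976,NA
acidity,15,2,0.0445,0.978,NA
acidity,25,0,0.0344,0.953,8.94
acidity,25,1,0.0413,0.979,NA
acidity,25,2,0.0510,0.991,NA
ffa,5,0,0.0191,0.898,10.99
ffa,5,1,0.0329,0.862,NA
ffa,5,2,0.0583,0.808,NA
ffa,15,0,0.0255,0.945,8.24
ffa,15,1,0.0412,0.889,NA
ffa,15,2,0.0690,0.819,NA
ffa,25,0,0.0305,0.970,6.89
ffa,25,1,0.0442,0.932,NA
ffa,25,2,0.0664,0.868,NA
tba,5,0,0.0016,0.960,6.72
tba,5,1,0.0489,0.911,NA
tba,5,2,1.5344,0.845,NA
tba,15,0,0.0021,0.970,5.12
tba,15,1,0.0573,0.916,NA
tba,15,2,1.6530,0.822,NA
tba,25,0,0.0027,0.972,3.98
tba,25,1,0.0659,0.907,NA
tba,25,2,1.7848,0.798,NA
total_plate_count,5,0,0.1646,0.974,9.33
total_plate_count,5,1,0.0382,0.961,NA
total_plate_count,5,2,0.0091,0.925,NA
total_plate_count,15,0,0.2066,0.932,7.43
total_plate_count,15,1,0.0451,0.888,NA
total_plate_count,15,2,0.0102,0.833,NA
total_plate_count,25,0,0.2322,0.956,6.61
total_plate_count,25,1,0.0491,0.915,NA
total_plate_count,25,2,0.0108,0.857,NA
yeast_mold,5,0,0.1715,0.888,6.43
yeast_mold,5,1,0.0541,0.912,NA
yeast_mold,5,2,0.0178,0.922,NA
yeast_mold,15,0,0.1816,0.854,6.07
yeast_mold,15,1,0.0561,0.894,NA
yeast_mold,15,2,0.0181,0.920,NA
yeast_mold,25,0,0.2403,0.901,4.59
yeast_mold,25,1,0.6560,0.958,NA
yeast_mold,25,2,0.0191,0.989,NA
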