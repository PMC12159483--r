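index_name,temperature_C,day,value,units,direction
anthocyanin,5,0,37.91,umol/100g,decreasing
anthocyanin,5,3,37.36,umol/100g,decreasing
anthocyanin,5,6,37.07,umol/100g,decreasing
anthocyanin,5,9,36.67,umol/100g,decreasing
anthocyanin,5,12,36.25,umol/100g,decreasing
anthocyanin,5,15,35.39,umol/100g,decreasing
anthocyanin,15,0,37.91,umol/100g,decreasing
anthocyanin,15,3,37.31,umol/100g,decreasing
anthocyanin,15,6,37.09,umol/100g,decreasing
anthocyanin,15,9,36.79,umol/100g,decreasing
anthocyanin,15,12,36.09,umol/100g,decreasing
anthocyanin,15,15,35.19,umol/100g,decreasing
anthocyanin,25,0,37.91,umol/100g,decreasing
anthocyanin,25,3,36.99,umol/100g,decreasing
anthocyanin,25,6,36.14,umol/100g,decreasing
anthocyanin,25,9,35.96,umol/100g,decreasing
anthocyanin,25,12,35.31,umol/100g,decreasing
anthocyanin,25,15,34.96,umol/100g,decreasing
total_phenol_content,5,0,44.14,mg GAE/100g,decreasing
total_phenol_content,5,3,44.27,mg GAE/100g,decreasing
total_phenol_content,5,6,43.76,mg GAE/100g,decreasing
total_phenol_content,5,9,43.15,mg GAE/100g,decreasing
total_phenol_content,5,12,42.55,mg GAE/100g,decreasing
total_phenol_content,5,15,42.15,mg GAE/100g,decreasing
total_phenol_content,15,0,44.14,mg GAE/100g,decreasing
total_phenol_content,15,3,43.17,mg GAE/100g,decreasing
total_phenol_content,15,6,42.43,mg GAE/100g,decreasing
total_phenol_content,15,9,41.92,mg GAE/100g,decreasing
total_phenol_content,15,12,41.33,mg GAE/100g,decreasing
total_phenol_content,15,15,40.96,mg GAE/100g,decreasing
total_phenol_content,25,0,44.14,mg GAE/100g,decreasing
total_phenol_content,25,3,43.10,mg GAE/100g,decreasing
total_phenol_content,25,6,42.42,mg GAE/100g,decreasing
total_phenol_content,25,9,42.09,mg GAE/100g,decreasing
total_phenol_content,25,12,40.34,mg GAE/100g,decreasing
total_phenol_content,25,15,40.19,mg GAE/100g,decreasing
total_flavonoid_content,5,0,22.62,mg QUE/100g,decreasing
total_flavonoid_content,5,3,22.20,mg QUE/100g,decreasing
total_flavonoid_content,5,6,21.93,mg QUE/100g,decreasing
total_flavonoid_content,5,9,21.52,mg QUE/100g,decreasing
total_flavonoid_content,5,12,21.11,mg QUE/100g,decreasing
total_flavonoid_content,5,15,20.42,mg QUE/100g,decreasing
total_flavonoid_content,15,0,22.62,mg QUE/100g,decreasing
total_flavonoid_content,15,3,22.10,mg QUE/100g,decreasing
total_flavonoid_content,15,6,21.74,mg QUE/100g,decreasing
total_flavonoid_content,15,9,21.22,mg QUE/100g,decreasing
total_flavonoid_content,15,12,20.78,mg QUE/100g,decreasing
total_flavonoid_content,15,15,20.11,mg QUE/100g,decreasing
total_flavonoid_content,25,0,22.62,mg QUE/100g,decreasing
total_flavonoid_content,25,3,22.25,mg QUE/100g,decreasing
total_flavonoid_content,25,6,21.57,mg QUE/100g,decreasing
total_flavonoid_content,25,9,21.02,mg QUE/100g,decreasing
total_flavonoid_content,25,12,20.32,mg QUE/100g,decreasing
total_flavonoid_content,25,15,19.89,mg QUE/100g,decreasing
ascorbic_acid,5,0,59.32,mg/100g,decreasing
ascorbic_acid,5,3,59.17,mg/100g,decreasing
ascorbic_acid,5,6,58.56,mg/100g,decreasing
ascorbic_acid,5,9,57.56,mg/100g,decreasing
ascorbic_acid,5,12,57.10,mg/100g,decreasing
ascorbic_acid,5,15,56.75,mg/100g,decreasing
ascorbic_acid,15,0,59.32,mg/100g,decreasing
ascorbic_acid,15,3,58.62,mg/100g,decreasing
ascorbic_acid,15,6,58.07,mg/100g,decreasing
ascorbic_acid,15,9,56.22,mg/100g,decreasing
ascorbic_acid,15,12,55.48,mg/100g,decreasing
ascorbic_acid,15,15,52.59,mg/100g,decreasing
ascorbic_acid,25,0,59.32,mg/100g,decreasing
ascorbic_acid,25,3,56.66,mg/100g,decreasing
ascorbic_acid,25,6,55.43,mg/100g,decreasing
ascorbic_acid,25,9,51.33,mg/100g,decreasing
ascorbic_acid,25,12,49.20,mg/100g,decreasing
ascorbic_acid,25,15,47.65,mg/100g,decreasing
ffa,5,0,0.42,ug/g,increasing
ffa,5,3,0.57,ug/g,increasing
ffa,5,6,0.60,ug/g,increasing
ffa,5,9,0.63,ug/g,increasing
ffa,5,12,0.66,ug/g,increasing
ffa,5,15,0.77,ug/g,increasing
ffa,15,0,0.42,ug/g,increasing
ffa,15,3,0.59,ug/g,increasing
ffa,15,6,0.67,ug/g,increasing
ffa,15,9,0.70,ug/g,increasing
ffa,15,12,0.78,ug/g,increasing
ffa,15,15,0.84,ug/g,increasing
ffa,25,0,0.46,ug/g,increasing
ffa,25,3,0.63,ug/g,increasing
ffa,25,6,0.71,ug/g,increasing
ffa,25,9,0.77,ug/g,increasing
ffa,25,12,0.84,ug/g,increasing
ffa,25,15,0.97,ug/g,increasing
tba,5,0,0.022,,increasing
tba,5,3,0.029,,increasing
tba,5,6,0.037,,increasing
tba,5,9,0.040,,increasing
tba,5,12,0.043,,increasing
tba,5,15,0.047,,increasing
tba,15,0,0.022,,increasing
tba,15,3,0.034,,increasing
tba,15,6,0.037,,increasing
tba,15,9,0.043,,increasing
tba,15,12,0.048,,increasing
tba,15,15,0.057,,increasing
tba,25,0,0.022,,increasing
tba,25,3,0.036,,increasing
tba,25,6,0.041,,increasing
tba,25,9,0.051,,increasing
tba,25,12,0.054,,increasing
tba,25,15,0.065,,increasing
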