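analysis,grouping,tolerance_days,method,tp,fp,tn,fn,sensitivity_pct,specificity_pct,ppv_pct,npv_pct,accuracy_pct,accuracy_ci_low_pct,accuracy_ci_high_pct,f_score,f_ci_low,f_ci_high
confirmation,combined,1,tos,86,53,43,23,79,45,62,65,62.9,55.9,69.6,0.69,0.60,0.77
confirmation,combined,1,sws,88,63,45,9,91,42,58,83,64.9,57.9,71.4,0.71,0.62,0.79
confirmation,combined,3,tos,119,20,43,23,84,68,86,65,79.0,72.8,84.4,0.85,0.78,0.90
confirmation,combined,3,sws,140,11,45,9,94,80,93,83,90.2,85.3,93.9,0.93,0.88,0.97
confirmation,training,1,tos,43,23,16,11,80,41,65,59,63.4,52.8,73.2,0.72,0.59,0.83
confirmation,training,1,sws,47,26,18,2,96,41,64,90,69.9,59.5,79.0,0.77,0.65,0.87
confirmation,training,3,tos,55,11,16,11,83,59,83,59,76.3,66.4,84.5,0.83,0.72,0.91
confirmation,training,3,sws,71,2,18,2,97,90,97,90,95.7,89.4,98.8,0.97,0.90,1.00
confirmation,additional,1,tos,43,30,27,12,78,47,59,69,62.5,52.9,71.5,0.67,0.54,0.78
confirmation,additional,1,sws,41,37,27,7,85,42,53,79,60.7,51.0,69.8,0.65,0.52,0.77
confirmation,additional,3,tos,64,9,27,12,84,75,88,69,81.3,72.8,88.0,0.86,0.76,0.93
confirmation,additional,3,sws,69,9,27,7,91,75,88,79,85.7,77.8,91.6,0.90,0.81,0.95
confirmation,arm,1,tos,61,41,33,19,76,45,60,63,61.0,52.9,68.8,0.67,0.56,0.77
confirmation,arm,1,sws,61,52,34,7,90,40,54,83,61.7,53.5,69.4,0.67,0.57,0.77
confirmation,arm,3,tos,87,15,33,19,82,69,85,63,77.9,70.5,84.2,0.84,0.75,0.90
confirmation,arm,3,sws,103,10,34,7,94,77,91,83,89.0,82.9,93.4,0.92,0.86,0.97
confirmation,wrist,1,tos,25,12,10,4,86,45,68,71,68.6,54.1,80.9,0.76,0.58,0.89
confirmation,wrist,1,sws,27,11,11,2,93,50,71,85,74.5,60.4,85.7,0.81,0.63,0.92
confirmation,wrist,3,tos,32,5,10,4,89,67,86,71,82.4,69.1,91.6,0.88,0.73,0.96
confirmation,wrist,3,sws,37,1,11,2,95,92,97,85,94.1,83.8,98.8,0.96,0.84,1.00
confirmation,prior_diagnosis,1,tos,49,27,28,15,77,51,64,65,64.7,55.4,73.2,0.70,0.58,0.80
confirmation,prior_diagnosis,1,sws,48,35,30,6,89,46,58,83,65.5,56.3,74.0,0.70,0.58,0.81
confirmation,prior_diagnosis,3,tos,64,12,28,15,81,70,84,65,77.3,68.7,84.5,0.83,0.72,0.90
confirmation,prior_diagnosis,3,sws,76,7,30,6,93,81,92,83,89.1,82.0,94.1,0.92,0.84,0.97
confirmation,no_diagnosis,1,tos,24,15,8,6,80,35,62,57,60.4,46.0,73.5,0.70,0.52,0.84
confirmation,no_diagnosis,1,sws,27,15,8,3,90,35,64,73,66.0,51.7,78.5,0.75,0.58,0.88
confirmation,no_diagnosis,3,tos,36,3,8,6,86,73,92,57,83.0,70.2,91.9,0.89,0.75,0.97
confirmation,no_diagnosis,3,sws,41,1,8,3,93,89,98,73,92.5,81.8,97.9,0.95,0.84,0.99
confirmation,late_ovulation,1,tos,28,14,0,11,72,NA,67,NA,52.8,38.6,66.7,0.69,0.53,0.83
confirmation,late_ovulation,1,sws,31,18,0,4,89,NA,63,NA,58.5,44.1,71.9,0.74,0.58,0.86
confirmation,late_ovulation,3,tos,39,3,0,11,78,NA,93,NA,73.6,59.7,84.7,0.85,0.71,0.94
confirmation,late_ovulation,3,sws,46,3,0,4,92,NA,94,NA,86.8,74.7,94.5,0.93,0.82,0.98
confirmation,early_normal,1,tos,58,35,0,12,83,NA,62,NA,55.2,45.2,65.0,0.71,0.60,0.81
confirmation,early_normal,1,sws,57,43,0,5,92,NA,57,NA,54.3,44.3,64.0,0.70,0.59,0.80
confirmation,early_normal,3,tos,80,13,0,12,87,NA,86,NA,76.2,66.9,84.0,0.86,0.78,0.93
confirmation,early_normal,3,sws,94,6,0,5,95,NA,94,NA,89.5,82.0,94.7,0.94,0.88,0.98
prediction,all,3,vs,54,31,0,0,100,NA,64,NA,63.5,52.4,73.7,0.78,0.66,0.87
prediction,all,3,tos,39,35,0,11,78,NA,53,NA,45.9,35.0,57.0,0.63,0.50,0.75
prediction,all,3,sws,51,34,0,0,100,NA,60,NA,60.0,48.8,70.5,0.75,0.63,0.85
prediction,prior_diagnosis,3,vs,28,19,0,0,100,NA,60,NA,59.6,44.3,73.6,0.75,0.58,0.87
prediction,prior_diagnosis,3,tos,20,20,0,7,74,NA,50,NA,42.6,28.3,57.8,0.60,0.41,0.76
prediction,prior_diagnosis,3,sws,24,23,0,0,100,NA,51,NA,51.1,36.1,65.9,0.68,0.50,0.82
prediction,no_diagnosis,3,vs,16,8,0,0,100,NA,67,NA,66.7,44.7,84.4,0.80,0.56,0.94
prediction,no_diagnosis,3,tos,10,10,0,4,71,NA,50,NA,41.7,22.1,63.4,0.59,0.33,0.82
prediction,no_diagnosis,3,sws,15,9,0,0,100,NA,63,NA,62.5,40.6,81.2,0.77,0.53,0.93
prediction,late_ovulation,3,vs,11,14,0,0,100,NA,44,NA,44.0,24.4,65.1,0.61,0.36,0.83
prediction,late_ovulation,3,tos,8,14,0,3,73,NA,36,NA,32.0,14.9,53.5,0.48,0.24,0.74
prediction,late_ovulation,3,sws,11,14,0,0,100,NA,44,NA,44.0,24.4,65.1,0.61,0.36,0.83
prediction,early_normal,3,vs,43,17,0,0,100,NA,72,NA,71.7,58.6,82.5,0.83,0.71,0.92
prediction,early_normal,3,tos,31,21,0,8,79,NA,60,NA,51.7,38.4,64.8,0.68,0.53,0.81
prediction,early_normal,3,sws,40,20,0,0,100,NA,67,NA,66.7,53.3,78.3,0.80,0.66,0.90
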