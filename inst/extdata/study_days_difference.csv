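analysis,grouping,method,n,mean_days,sd_days,ci_low,ci_high
confirmation,combined,tos,158,-3.26,1.93,-3.56,-2.96
confirmation,combined,sws,158,-1.51,1.83,-1.80,-1.23
confirmation,training,tos,75,-4.05,1.31,-4.35,-3.76
confirmation,training,sws,75,-1.29,1.05,-1.53,-1.06
confirmation,additional,tos,83,-2.52,1.44,-2.83,-2.21
confirmation,additional,sws,83,-1.71,1.51,-2.04,-1.39
confirmation,arm,tos,118,-3.78,1.70,-4.09,-3.47
confirmation,arm,sws,118,-1.65,1.66,-1.95,-1.35
confirmation,wrist,tos,40,-1.69,0.94,-1.98,-1.40
confirmation,wrist,sws,40,-1.10,0.79,-1.35,-0.85
confirmation,prior_diagnosis,tos,88,-2.98,1.35,-3.26,-2.69
confirmation,prior_diagnosis,sws,88,-1.24,1.45,-1.54,-0.93
confirmation,no_diagnosis,tos,45,-3.45,0.98,-3.74,-3.17
confirmation,no_diagnosis,sws,45,-2.93,0.73,-3.15,-2.72
confirmation,late_ovulation,tos,53,-7.09,0.84,-7.32,-6.87
confirmation,late_ovulation,sws,53,-3.26,1.02,-3.54,-2.99
confirmation,early_normal,tos,105,-1.28,1.75,-1.62,-0.95
confirmation,early_normal,sws,105,-0.63,1.53,-0.92,-0.34
prediction,all,vs,85,-0.34,7.22,-1.88,1.19
prediction,all,tos,85,-1.74,7.20,-3.27,-0.21
prediction,all,sws,85,-0.66,7.43,-2.24,0.92
prediction,prior_diagnosis,vs,47,-0.34,9.00,-2.91,2.23
prediction,prior_diagnosis,tos,47,-2.20,9.03,-4.78,0.38
prediction,prior_diagnosis,sws,47,-0.94,9.27,-3.59,1.71
prediction,no_diagnosis,vs,24,-1.25,4.46,-3.03,0.53
prediction,no_diagnosis,tos,24,-1.85,4.35,-3.59,-0.11
prediction,no_diagnosis,sws,24,-0.96,4.76,-2.86,0.95
prediction,late_ovulation,vs,25,-4.80,11.06,-9.14,-0.46
prediction,late_ovulation,tos,25,-5.50,11.07,-9.84,-1.16
prediction,late_ovulation,sws,25,-4.88,11.36,-9.33,-0.43
prediction,early_normal,vs,60,1.52,3.52,0.62,2.41
prediction,early_normal,tos,60,-0.15,4.15,-1.20,0.90
prediction,early_normal,sws,60,1.10,3.92,0.11,2.09
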