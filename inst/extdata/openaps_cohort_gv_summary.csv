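metric,min,max,average,q1,q2,q3,iqr
interday_sd,14.71,77.33,49.75,43.13,49.34,58.10,14.97
roc_sd,0.61,2.69,1.42,1.15,1.41,1.66,0.51
interday_cv,16.86,44.94,35.43,32.42,35.87,38.47,6.05
tir,49.75,98.45,77.26,71.18,77.91,84.07,12.89
tor_below_70,0.23,16.97,4.01,1.79,3.22,5.61,3.83
tor_above_180,0.05,49.67,18.74,12.72,17.14,25.52,12.81
lbgi,0.13,3.82,1.09,0.64,0.95,1.42,0.78
hbgi,0.03,13.25,4.36,2.83,3.95,5.89,3.06
j_index,10.39,73.93,36.42,29.71,35.49,43.84,14.14
gmi,5.40,7.96,6.63,6.38,6.63,6.92,0.53
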