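parameter,site,group,median,iqr,min,max,range,skew,kurtosis
hrw_a,artery,hold_out,6.186,4.929,0.44,43.501,43.061,1.747,4.765
a_n1,artery,hold_out,-0.526,2.988,-9.462,10.746,20.208,-0.448,0.963
b_n1,artery,hold_out,-2.049,1.828,-15.195,6.387,21.582,-1,4.077
a_n2,artery,hold_out,0.318,1.026,-3.124,5.96,9.083,0.899,2.352
b_n2,artery,hold_out,0.05,0.878,-4.221,9.6,13.821,0.783,6.561
hrw_a,vein,hold_out,7.028,6.123,0.38,64.241,63.861,2.865,11.725
a_n1,vein,hold_out,1.664,2.391,-22.936,21.63,44.566,0.995,7.928
b_n1,vein,hold_out,-2.24,2.172,-25.153,11.503,36.657,-2.769,14.537
a_n2,vein,hold_out,-0.228,1.055,-7.551,8.557,16.109,-0.273,4.622
b_n2,vein,hold_out,0.203,0.815,-13.343,10.293,23.635,0.389,22.033
hrw_a,artery,cautionary,4.099,2.256,1.391,14.847,13.456,1.566,3.716
a_n1,artery,cautionary,-0.954,0.748,-5.429,1.522,6.951,-0.552,3.356
b_n1,artery,cautionary,-1.304,0.847,-4.257,1.387,5.644,-0.892,1.865
a_n2,artery,cautionary,0.338,0.624,-1.081,2.133,3.215,0.235,0.285
b_n2,artery,cautionary,-0.046,0.817,-2.383,2.065,4.448,-0.181,0.424
hrw_a,vein,cautionary,6.127,4.425,1.306,32.956,31.65,2.093,4.68
a_n1,vein,cautionary,1.197,3.466,-5.257,12.665,17.922,0.984,1.476
b_n1,vein,cautionary,-2.102,1.777,-11.201,2.942,14.144,-1.889,4.507
a_n2,vein,cautionary,-0.039,0.754,-2.578,1.929,4.506,-0.621,1.102
b_n2,vein,cautionary,0.367,0.952,-2.368,4.242,6.61,0.559,1.404
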