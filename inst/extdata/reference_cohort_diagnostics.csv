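case_id,vessel,icp_measured,n,n_iop_levels,laterality,mean,median,mode,sd,skew,kurtosis,di_icp,ads,ks,dist_type,diff_icp_md,sent,subset
case_1,arterial,22,2348,14,2,26.59,25.18,24.98,8.251264,1.05,4.56,13.95,15.808,0.057,gamma,3.18,5.587466,hold_out
case_2,arterial,32,248,9,1,24.13,24.05,24.45,4.99726,0.7,6.02,16.69,1.144,0.06,logistic,7.95,5.381761,hold_out
case_3,arterial,20,701,13,2,24.52,21.63,20.07,8.060139,1.3,4.12,15.19,14.455,0.124,beta,1.63,5.555466,hold_out
case_4,arterial,32,1026,15,2,31.86,30.66,28.7,8.229153,0.32,2.81,10.08,1.993,0.034,beta,1.34,5.657664,hold_out
case_5,arterial,17,1396,12,2,23.26,22.8,21.36,5.797218,0.52,5.49,14.72,6.047,0.064,logistic,5.8,5.171197,hold_out
case_6,arterial,27,1447,15,2,28.25,25.12,24.05,8.797857,1.43,4.76,17.63,36.552,0.142,logistic,1.88,5.511104,hold_out
case_7,arterial,26,446,7,1,28.65,25.59,23.38,8.791855,0.76,2.94,10.7,5.401,0.102,beta,0.41,5.688154,hold_out
case_8,arterial,11,358,9,1,33.05,33.22,44.1,13.30743,-0.11,1.83,3.27,8.424,0.141,uniform,22.22,5.795639,cautionary
case_9,arterial,8,653,9,1,41.82,45.09,39.09,14.85954,0.02,2.18,4.39,6.426,0.085,uniform,37.09,5.848207,cautionary
case_1,venous,22,2020,14,2,27.77,26.34,24.47,8.522667,1.83,8.04,12.39,11.76,0.056,gamma,4.34,5.353739,hold_out
case_2,venous,32,787,9,1,30.9,29.13,27.77,9.451438,1.59,7.22,12.53,5.869,0.069,lognormal,2.87,5.46967,hold_out
case_3,venous,20,837,13,2,24.18,23.21,22.98,6.10234,1.5,6.73,17.68,3.651,0.056,lognormal,3.21,5.392312,hold_out
case_4,venous,32,936,15,2,31.29,30.55,30.2,7.643098,0.55,4.19,13.47,4.784,0.071,lognormal,1.45,5.548359,hold_out
case_5,venous,17,1936,12,2,22.78,23,23.33,5.714698,0.29,4.93,17.84,38.071,0.098,logistic,6,5.353076,hold_out
case_6,venous,27,3617,15,2,26.26,25.09,24.01,6.510826,1.3,5.83,15.79,13.964,0.037,logistic,1.91,5.48403,hold_out
case_7,venous,26,742,7,1,20.7,18.44,15.91,6.921495,1.12,3.98,12.97,11.765,0.099,beta,7.56,5.465993,hold_out
case_8,venous,11,939,9,1,25.77,26.01,26.17,4.203027,-0.58,4.77,24.46,23.953,0.116,logistic,15.01,5.398153,cautionary
case_9,venous,8,474,9,1,33.67,31.2,27.41,10.37868,0.81,2.67,8.22,12.124,0.147,beta,23.2,5.592257,cautionary
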