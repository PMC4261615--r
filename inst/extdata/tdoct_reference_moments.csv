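layer,feature,healthy_mean,healthy_sd,mdr_mean,mdr_sd,auroc,auroc_se,ci_low,ci_high,cutoff,plr
RNFL,thickness,42.02,2.11,41.38,2.93,0.598,0.059,0.483,0.713,41.03,1.51
GCL+IPL,thickness,78.30,4.09,71.80,8.22,0.756,0.050,0.657,0.855,75.88,2.90
INL,thickness,35.02,1.60,35.05,2.76,0.508,0.061,0.388,0.627,34.86,1.33
OPL,thickness,41.30,2.49,36.07,3.45,0.878,0.041,0.797,0.958,38.24,6.48
ONL+IS,thickness,86.41,5.21,88.39,8.21,0.394,0.055,0.285,0.503,86.86,1.07
OS,thickness,16.27,3.06,14.40,2.20,0.688,0.049,0.591,0.784,14.59,8.22
RPE,thickness,12.71,1.32,12.76,1.09,0.481,0.054,0.375,0.588,12.40,3.52
RNFL,fd,1.74,0.04,1.78,0.10,0.393,0.056,0.284,0.503,1.74,1.02
GCL+IPL,fd,1.68,0.01,1.58,0.05,0.953,0.025,0.905,1.002,1.66,15.53
INL,fd,1.78,0.01,1.76,0.03,0.785,0.053,0.680,0.890,1.77,3.02
OPL,fd,1.51,0.01,1.56,0.04,0.111,0.041,0.031,0.190,1.52,1.02
ONL+IS,fd,1.78,0.03,1.79,0.04,0.336,0.055,0.228,0.444,1.78,2.96
OS,fd,1.70,0.02,1.73,0.04,0.268,0.047,0.177,0.359,1.71,1.00
RPE,fd,1.68,0.01,1.68,0.01,0.433,0.056,0.323,0.543,1.68,1.09
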