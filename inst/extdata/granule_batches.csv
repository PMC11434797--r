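batch,roll_pressure_bar,roll_gap_mm,alpha,lambda1_um,lambda2_um,k1,k2,mu1_printed_um,mu2_printed_um,mu_gsd_printed_um,ribbon_density
1,30,2,0.54,524,1055,2.25,5.32,457,991,696,0.640
2,30,3,0.57,518,1019,2.25,5.43,325,999,667,0.613
3,60,2,0.46,541,1170,2.24,4.98,479,1074,800,0.739
4,60,3,0.58,517,1009,2.26,5.46,458,931,658,0.708
5,90,2,0.44,546,1202,2.23,4.89,484,1102,830,0.803
6,90,3,0.50,533,1114,2.24,5.15,472,1024,747,0.770
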