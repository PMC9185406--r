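subject,pcc_mean,pcc_sd,nrmse_mean,nrmse_sd
1,0.88,0.15,29.26,10.52
2,0.98,0.03,19.86,11.07
3,0.81,0.14,30.34,16.88
4,0.95,0.30,51.65,6.42
5,0.97,0.25,49.89,3.48
6,0.89,0.30,24.66,12.83
7,0.86,0.29,17.45,4.51
8,0.99,0.12,61.34,2.77
9,0.88,0.15,34.21,5.46
10,0.97,0.15,29.78,5.87
11,0.98,0.12,25.65,12.83
12,0.83,0.04,12.45,6.53
13,0.82,0.06,34.65,3.97
14,0.99,0.00,21.45,3.01
15,0.89,0.04,57.65,16.88
16,0.88,0.15,26.16,10.71
17,0.87,0.29,34.07,3.46
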