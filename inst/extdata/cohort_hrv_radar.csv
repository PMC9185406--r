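parameter,ref,exp
mean_nni,28663.5,27050.8
sd1,334.8,127.89
sdnn,17257.6,15679.9
rmssd,761.1,797.5
sdsd,323.3,222.3
nn20,80.0,72.0
peak_freq,0.01,0.01
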