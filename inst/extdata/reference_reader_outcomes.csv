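outcome,unaided_mean,unaided_sd,unaided_var,unaided_ci,aided_mean,aided_sd,aided_var,aided_ci
time_s,22.9,2.3,5.4,1.503,14.7,1.3,1.7,0.849
auc,0.759,0.07,0.01,0.046,0.88,0.05,0.01,0.033
sensitivity,0.769,0.02,0,0.013,0.857,0.02,0,0.013
specificity,0.946,0.01,0,0.007,0.974,0.01,0,0.007
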