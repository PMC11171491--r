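label,sensitivity,specificity,npv,ppv,auc,auc_lo,auc_hi
pleural_effusion,0.972,0.87,0.984,0.789,0.9362,0.9237,0.9477
consolidation,0.93,0.886,0.962,0.803,0.9161,0.9024,0.9292
cardiomegaly,0.978,0.839,0.987,0.752,0.9464,0.9361,0.9558
pulmonary_nodule,0.988,0.795,0.9925,0.707,0.9582,0.9497,0.9659
pneumothorax,0.976,0.812,0.9854,0.7219,0.9457,0.9355,0.9549
acute_pulmonary_edema,0.942,0.859,0.9673,0.7696,0.9123,0.8981,0.92556
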