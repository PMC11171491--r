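label,tp,fn,fp,tn
pleural_effusion,486,14,130,870
consolidation,465,35,114,886
cardiomegaly,489,11,161,839
pulmonary_nodule,494,6,205,795
pneumothorax,488,12,188,812
acute_pulmonary_edema,471,29,141,859
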