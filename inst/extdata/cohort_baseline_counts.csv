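variable,total,mild,severe
subjects,70,37,33
deaths,6,0,6
delayed_edema,8,0,8
males,42,NA,NA
age_le_24mo,22,NA,NA
age_gt_24mo,48,NA,NA
trauma_mva,12,1,11
trauma_fall,15,5,10
trauma_other,43,31,11
marshall_i,34,33,1
marshall_ii,6,4,2
marshall_iii,9,0,9
marshall_iv,1,0,1
marshall_v,0,0,0
marshall_vi,20,0,20
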