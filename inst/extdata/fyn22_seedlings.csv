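trait,group,mean,sd,n
root_length_mm,control,9.92,0.49,20
root_length_mm,treatment,11.58,0.47,20
shoot_length_mm,control,10.08,0.4,20
shoot_length_mm,treatment,14.95,1.29,20
fresh_weight_mg,control,127.33,36.05,20
fresh_weight_mg,treatment,150.83,36.35,20
dry_weight_mg,control,20.76,3.41,20
dry_weight_mg,treatment,25.32,2.55,20
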