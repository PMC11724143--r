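drug,dose_mg,class,mean_delta_sbp,sd_delta_sbp,conventional
irbesartan,150,ARB,10.3,2.0,TRUE
irbesartan,300,ARB,12.4,2.0,TRUE
ramipril,5,ACEi,8.5,2.0,TRUE
ramipril,10,ACEi,10.2,2.0,TRUE
ramipril,1.25,ACEi,5.5,2.0,FALSE
amlodipine,5,CCB,8.8,2.0,TRUE
amlodipine,10,CCB,10.6,2.0,TRUE
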