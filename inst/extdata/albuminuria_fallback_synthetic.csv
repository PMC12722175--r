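modality,sex,diabetes,hypertension,category,value
pcr,any,any,any,,0.65
dipstick,any,any,any,neg,15
dipstick,any,any,any,trace,60
dipstick,any,any,any,1+,200
dipstick,any,any,any,2+,500
dipstick,any,any,any,3+,1500
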