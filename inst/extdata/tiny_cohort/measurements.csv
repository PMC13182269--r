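subject_id,time,feature_id,value
child_a,0.5,ALPL_like,6.25
child_a,2,ALPL_like,6.75
child_b,1,ALPL_like,5.5
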