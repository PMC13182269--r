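subject_id,event_time,status,group
child_a,4.2,1,case
child_b,10,0,control
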