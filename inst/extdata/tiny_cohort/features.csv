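feature_id,n_peptides,n_missing
ALPL_like,7,0
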