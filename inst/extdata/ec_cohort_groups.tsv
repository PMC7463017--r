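group	n	residual_disease_excluded
eec_stage_i	57	0
eec_stage_ii_iv	12	1
usc	14	4
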