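# Clinicopathological counts for the three tumour groups of the study
# cohort (57 stage I EEC, 12 stage II-IV EEC, 14 USC). printed_pct is the
# percentage as published, stored verbatim; it is NA where the source
# prints a dash. Recurrence rows count patients without residual disease
# only (denominators 57 / 11 / 10). Data erratum, kept as printed: the USC
# recurrence rows are internally inconsistent ("no" 4 = 40% of 10 but
# "distant" 5 printed as 60%), and the USC LVSI rows sum to 13 of n = 14.
group	variable	level	count	printed_pct
eec_stage_i	treatment	lymphadenectomy	8	14
eec_stage_i	treatment	radiotherapy	15	26
eec_stage_i	treatment	chemotherapy	0	NA
eec_stage_i	figo	I	57	100
eec_stage_i	figo	II	0	NA
eec_stage_i	figo	III	0	NA
eec_stage_i	figo	IV	0	NA
eec_stage_i	grade	low	51	89
eec_stage_i	grade	high	6	11
eec_stage_i	myometrial_invasion	lt_half	42	74
eec_stage_i	myometrial_invasion	ge_half	15	26
eec_stage_i	lvsi	no	46	81
eec_stage_i	lvsi	yes	11	19
eec_stage_i	recurrence	yes	8	14
eec_stage_i	recurrence	distant	5	9
eec_stage_i	recurrence	no	49	86
eec_stage_i	ec_mortality	yes	4	7
eec_stage_i	ec_mortality	no	53	93
eec_stage_ii_iv	treatment	lymphadenectomy	7	58
eec_stage_ii_iv	treatment	radiotherapy	10	83
eec_stage_ii_iv	treatment	chemotherapy	3	25
eec_stage_ii_iv	figo	I	0	NA
eec_stage_ii_iv	figo	II	4	33
eec_stage_ii_iv	figo	III	5	42
eec_stage_ii_iv	figo	IV	3	25
eec_stage_ii_iv	grade	low	7	58
eec_stage_ii_iv	grade	high	5	42
eec_stage_ii_iv	myometrial_invasion	lt_half	3	25
eec_stage_ii_iv	myometrial_invasion	ge_half	9	75
eec_stage_ii_iv	lvsi	no	3	25
eec_stage_ii_iv	lvsi	yes	9	75
eec_stage_ii_iv	recurrence	yes	6	55
eec_stage_ii_iv	recurrence	distant	6	55
eec_stage_ii_iv	recurrence	no	5	46
eec_stage_ii_iv	ec_mortality	yes	5	42
eec_stage_ii_iv	ec_mortality	no	7	58
usc	treatment	lymphadenectomy	12	86
usc	treatment	radiotherapy	5	36
usc	treatment	chemotherapy	8	57
usc	figo	I	4	29
usc	figo	II	0	NA
usc	figo	III	3	21
usc	figo	IV	7	50
usc	grade	low	0	NA
usc	grade	high	14	100
usc	myometrial_invasion	lt_half	6	43
usc	myometrial_invasion	ge_half	8	57
usc	lvsi	no	5	36
usc	lvsi	yes	8	57
usc	recurrence	yes	6	60
usc	recurrence	distant	5	60
usc	recurrence	no	4	40
usc	ec_mortality	yes	8	57
usc	ec_mortality	no	6	43
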