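# Clinical cohort table: 29 diagnosis-relapse ALL patients.
# bmt_after_first_relapse: bone-marrow transplant performed after first relapse.
# time_to_second_relapse_months measured from diagnosis; na = no second relapse.
patient_id	immunophenotype	subtype_diagnosis	subtype_revised	risk_group	time_to_first_relapse_months	first_relapse_on_therapy	time_to_second_relapse_months	vital_status	bmt_after_first_relapse
ALL_5	BCP-ALL	KMT2A-rearranged	KMT2A-rearranged	Infant	28	Off	40	D	TRUE
ALL_202	BCP-ALL	KMT2A-rearranged	KMT2A-rearranged	Infant	5	On	na	D	FALSE
ALL_680	BCP-ALL	dic(9;20)	dic(9;20)	HR	35	Off	na	A	FALSE
ALL_205	BCP-ALL	normal	DUX4-rearranged	IR	65	Off	na	A	FALSE
ALL_831	BCP-ALL	HeH	HeH	HR	55	Off	na	A	FALSE
ALL_832	BCP-ALL	HeH	HeH	SR	39	Off	48	D	TRUE
ALL_837	BCP-ALL	HeH	HeH	SR	40	Off	na	A	FALSE
ALL_48	BCP-ALL	HeH	HeH	IR	38	Off	na	A	FALSE
ALL_210	BCP-ALL	HeH	HeH	SR	48	Off	na	A	FALSE
ALL_839	BCP-ALL	HeH	HeH	HR	20	On	na	A	FALSE
ALL_380	BCP-ALL	HeH	HeH	IR	47	Off	na	A	FALSE
ALL_464	BCP-ALL	HeH	HeH	HR	28	Off	na	D	FALSE
ALL_317	BCP-ALL	iAMP21	iAMP21	IR	44	Off	na	A	FALSE
ALL_838	BCP-ALL	normal	B-other group	IR	45	Off	na	D	FALSE
ALL_24	BCP-ALL	B-other group	B-other group	HR	27	Off	na	D	FALSE
ALL_128	BCP-ALL	B-other group	B-other group	IR	38	Off	61	D	FALSE
ALL_244	BCP-ALL	B-other group	MEF2D-rearranged	HR	10	On	19	D	FALSE
ALL_827	MPAL	ALL/AML	MPAL	HR	18	On	na	D	FALSE
ALL_834	BCP-ALL	normal	B-other group	SR	37	Off	64	D	FALSE
ALL_27	BCP-ALL	normal	B-other group	IR	85	Off	100	D	FALSE
ALL_833	T-ALL	T-ALL	T-ALL	HR	5	On	9	D	FALSE
ALL_836	T-ALL	T-ALL	T-ALL	HR	18	On	22	A	FALSE
ALL_358	T-ALL	T-ALL	T-ALL	HR	18	On	na	D	FALSE
ALL_388	T-ALL	T-ALL	T-ALL	HR	14	On	Na	A	FALSE
ALL_835	BCP-ALL	t(12;21)	t(12;21)	SR	53	Off	Na	A	FALSE
ALL_109	BCP-ALL	t(12;21)	t(12;21)	HR	24	Off	45	D	TRUE
ALL_124	BCP-ALL	t(12;21)	t(12;21)	SR	35	Off	Na	D	FALSE
ALL_257	BCP-ALL	normal	ZNF384-rearranged	IR	38	Off	Na	A	FALSE
ALL_8	BCP-ALL	B-other group	ZNF384-rearranged	IR	40	Off	Na	A	FALSE
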