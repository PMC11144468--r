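label	cohort	instrument	or	ci_low	ci_high	n_cases
urti	CKB	pcsk9_score	2.18	1.34	3.53	1095
urti	UKB	pcsk9_score	1.70	1.15	2.51	2364
urti	CKB	ldl_grs	1.11	0.88	1.38	NA
asthma	CKB	pcsk9_score	2.28	1.12	4.64	427
asthma	UKB	pcsk9_score	1.15	1.02	1.28	39269
carotid_plaque	CKB	pcsk9_score	0.61	0.45	0.83	8340
liver_disease	CKB	pcsk9_score	2.10	1.17	3.79	NA
copd_hospitalisation	CKB	pcsk9_score	1.38	1.08	1.76	6836
copd_incident_fatal	CKB	pcsk9_score	1.47	0.93	2.34	1632
copd_incident_nonfatal	CKB	pcsk9_score	1.38	1.05	1.80	5204
copd_exacerbation	CKB	pcsk9_score	1.91	1.12	3.24	2212
copd_exacerbation_fatal	CKB	pcsk9_score	3.61	1.71	7.60	730
copd_exacerbation_fatal	CKB	ldl_grs	0.92	0.75	1.19	NA
prevalent_copd	CKB	pcsk9_score	0.96	0.73	1.26	5105
move	CKB	pcsk9_score	0.80	0.67	0.95	15752
ischaemic_stroke	CKB	pcsk9_score	0.80	0.66	0.98	11467
intracerebral_haemorrhage	CKB	pcsk9_score	1.04	0.81	1.34	5906
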