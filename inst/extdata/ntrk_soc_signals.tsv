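soc	n_ent	n_laro	ror_ent	ror_low_ent	ror_high_ent	ror_laro	ror_low_laro	ror_high_laro	prr_ent	prr_laro	chi2_ent	chi2_laro	ic025_ent	ic025_laro
Nervous system disorders	304	199	2.99	2.64	3.39	2.18	1.88	2.54	2.61	2.01	326.03	108.46	-0.28	-0.66
General disorders and administration site conditions	243	248	0.84	0.73	0.97	1.07	0.94	1.23	0.87	1.06	6.12	1.03	-1.88	-1.58
Investigations	136	94	1.45	1.22	1.73	1.19	0.96	1.47	1.41	1.17	17.43	2.60	-1.17	-1.44
Gastrointestinal disorders	120	101	0.95	0.79	1.14	0.94	0.77	1.15	0.95	0.94	0.32	0.38	-1.74	-1.75
Injury, poisoning and procedural complications	105	102	0.53	0.43	0.64	0.63	0.51	0.77	0.56	0.65	41.83	21.04	-2.51	-2.28
Cardiac disorders	100	8	3.33	2.72	4.08	0.29	0.15	0.59	3.18	0.30	152.70	13.48	0.01	-3.41
Respiratory, thoracic and mediastinal disorders	95	61	1.32	1.07	1.62	0.99	0.77	1.28	1.30	0.99	6.77	0	-1.29	-1.68
Renal and urinary disorders	90	21	2.84	2.30	3.51	0.72	0.47	1.11	2.74	0.73	101.26	2.20	-0.22	-2.13
Musculoskeletal and connective tissue disorders	62	78	0.73	0.57	0.94	1.13	0.90	1.42	0.74	1.12	6.03	1.11	-2.10	-1.50
Infections and infestations	59	29	0.64	0.50	0.83	0.37	0.26	0.54	0.66	0.39	11.22	29.68	-2.27	-3.03
Metabolism and nutrition disorders	47	26	1.55	1.16	2.08	1.00	0.68	1.47	1.54	1.00	9.02	0	-1.05	-1.67
Psychiatric disorders	42	25	0.47	0.35	0.64	0.33	0.23	0.50	0.49	0.35	24.18	32.39	-2.71	-3.19
Neoplasms benign, malignant and unspecified (incl cysts and polyps)	42	179	0.59	0.43	0.80	3.67	3.13	4.29	0.60	3.31	11.94	300.84	-2.41	0.06
Skin and subcutaneous tissue disorders	38	33	0.40	0.29	0.55	0.41	0.29	0.57	0.41	0.42	33.70	28.10	-2.94	-2.92
Vascular disorders	33	17	1.10	0.78	1.55	0.66	0.41	1.07	1.09	0.67	0.27	2.88	-1.54	-2.25
Eye disorders	21	12	0.70	0.45	1.07	0.47	0.27	0.83	0.70	0.48	2.70	7.02	-2.18	-2.74
Blood and lymphatic system disorders	18	30	0.68	0.43	1.08	1.36	0.95	1.95	0.68	1.35	2.70	2.80	-2.22	-1.23
Hepatobiliary disorders	14	29	1.09	0.65	1.85	2.68	1.85	3.87	1.09	2.64	0.11	29.83	-1.54	-0.27
Surgical and medical procedures	11	35	0.50	0.27	0.90	1.94	1.39	2.72	0.50	1.92	5.59	15.55	-2.67	-0.73
Immune system disorders	7	2	0.37	0.18	0.78	0.12	0.03	0.48	0.38	0.12	7.38	12.92	-3.08	-4.71
Ear and labyrinth disorders	6	5	0.92	0.41	2.05	0.91	0.38	2.19	0.92	0.91	0.04	0.05	-1.79	-1.81
Endocrine disorders	6	0	1.44	0.65	3.21	NA	NA	NA	1.44	NA	0.80	NA	-1.14	NA
Reproductive system and breast disorders	2	0	0.19	0.05	0.78	NA	NA	NA	0.20	NA	6.64	NA	-4.02	NA
Congenital, familial and genetic disorders	2	3	0.48	0.12	1.91	0.84	0.27	2.62	0.48	0.84	1.14	0.09	-2.73	-1.91
Product issues	1	4	0.03	0.00	0.25	0.17	0.06	0.45	0.04	0.17	26.60	16.32	-6.48	-4.21
Social circumstances	1	2	0.13	0.02	0.92	0.31	0.08	1.24	0.13	0.31	5.82	3.08	-4.61	-3.35
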