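drug	block	category	n	total	printed_pct
entrectinib	Age (years)	<18	32	563	5.7
entrectinib	Age (years)	18-64	22	563	3.9
entrectinib	Age (years)	>64	2	563	0.3
entrectinib	Age (years)	Unknown	507	563	90.1
entrectinib	Sex	Female	286	563	50.8
entrectinib	Sex	Male	237	563	42.1
entrectinib	Sex	Unknown	40	563	7.1
entrectinib	Weight (kg)	<80	163	563	29.0
entrectinib	Weight (kg)	80-100	23	563	4.1
entrectinib	Weight (kg)	>100	13	563	2.3
entrectinib	Weight (kg)	Unknown	364	563	64.6
entrectinib	Reported countries	US	278	563	49.4
entrectinib	Reported countries	JP	139	563	24.7
entrectinib	Reported countries	DE	14	563	2.5
entrectinib	Reported countries	IL	13	563	2.3
entrectinib	Reported countries	FR	12	563	2.1
entrectinib	Reporter type	Consumer	180	563	32.0
entrectinib	Reporter type	Health professional	369	563	65.5
entrectinib	Reporter type	Unknown	14	563	2.5
entrectinib	Indications	Non-small cell lung cancer	167	563	29.7
entrectinib	Indications	Lung neoplasm malignant	107	563	19.0
entrectinib	Indications	Neoplasm	37	563	6.6
entrectinib	Indications	Neoplasm malignant	23	563	4.1
entrectinib	Indications	Lung adenocarcinoma	14	563	2.5
entrectinib	Serious outcomes	OT	229	518	44.2
entrectinib	Serious outcomes	HO	166	518	32.0
entrectinib	Serious outcomes	DE	103	518	19.9
entrectinib	Serious outcomes	LT	14	518	2.7
entrectinib	Serious outcomes	DS	6	518	1.2
larotrectinib	Age (years)	<18	7	524	1.3
larotrectinib	Age (years)	18-64	22	524	4.2
larotrectinib	Age (years)	>64	17	524	3.3
larotrectinib	Age (years)	Unknown	478	524	91.2
larotrectinib	Sex	Female	222	524	42.4
larotrectinib	Sex	Male	220	524	42.0
larotrectinib	Sex	Unknown	82	524	15.6
larotrectinib	Weight (kg)	<80	18	524	3.4
larotrectinib	Weight (kg)	80-100	5	524	1.0
larotrectinib	Weight (kg)	>100	1	524	0.2
larotrectinib	Weight (kg)	Unknown	500	524	95.4
larotrectinib	Reported countries	US	308	524	58.8
larotrectinib	Reported countries	FR	38	524	7.3
larotrectinib	Reported countries	MX	25	524	4.8
larotrectinib	Reported countries	CA	18	524	3.4
larotrectinib	Reported countries	CH	15	524	2.9
larotrectinib	Reporter type	Consumer	139	524	26.5
larotrectinib	Reporter type	Health professional	384	524	73.3
larotrectinib	Reporter type	Unknown	1	524	0.2
larotrectinib	Indications	Thyroid cancer	28	524	5.3
larotrectinib	Indications	Neoplasm malignant	19	524	3.6
larotrectinib	Indications	Lung neoplasm malignant	18	524	3.4
larotrectinib	Indications	Neoplasm	17	524	3.2
larotrectinib	Indications	Sarcoma	14	524	2.7
larotrectinib	Serious outcomes	OT	238	420	56.7
larotrectinib	Serious outcomes	HO	95	420	22.6
larotrectinib	Serious outcomes	DE	80	420	19.0
larotrectinib	Serious outcomes	LT	5	420	1.2
larotrectinib	Serious outcomes	DS	2	420	0.5
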