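drug	n_tto	median_days	shape	shape_low	shape_high	n_first_month	pct_first_month	n_over_year	pct_over_year
entrectinib	243	16	0.56	0.51	0.61	147	60.5	25	10.3
larotrectinib	113	44	0.73	0.62	0.84	53	46.9	10	8.9
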