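name	event	gamma	beta	r0	n_stations
miami-fort-lauderdale	irma	0.1841	0.0111	3.98	1369
fort-myers-naples	irma	0.1901	0.0089	2.90	76
tampa-st-petersburg	irma	0.1708	0.01	3.40	922
orlando	irma	0.2214	0.006	1.57	810
jacksonville	irma	0.2718	0.0097	1.61	453
wilmington	florence	0.0953	0.012	11.59	46
greenville-new-bern-washington	florence	0.1543	0.0143	8.91	130
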