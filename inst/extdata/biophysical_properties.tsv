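# Biophysical properties of rat, chicken and frog alpha4beta2, alpha7 and
# alpha9alpha10 nAChRs measured in Xenopus laevis oocytes (mean, SEM, n).
# Properties: ACh EC50 (uM; alpha4beta2 lists the high- and low-sensitivity
# dose-response components separately), desensitization (% current remaining
# 20 s after peak; 5 s for alpha7), Ca2+ modulation (I at 0.5 mM / I at 3 mM
# Ca2+), Ca2+ permeability (% current remaining after BAPTA-AM) and
# rectification (I+40mV / I-90mV).
receptor	species	property	mean	sem	n
a4b2	rat	EC50_high	3.11	2.11	3
a4b2	rat	EC50_low	159.76	35.67	4
a4b2	chicken	EC50_high	1.07	0.15	6
a4b2	chicken	EC50_low	66.00	9.76	4
a4b2	frog	EC50_high	0.75	0.02	7
a4b2	frog	EC50_low	143.71	51.89	5
a4b2	rat	desensitization	77.13	1.21	4
a4b2	chicken	desensitization	77.68	5.16	7
a4b2	frog	desensitization	72.70	3.04	10
a4b2	rat	ca_modulation	0.36	0.04	5
a4b2	chicken	ca_modulation	0.55	0.03	9
a4b2	frog	ca_modulation	0.60	0.08	5
a4b2	rat	ca_permeability	72.07	9.62	4
a4b2	chicken	ca_permeability	78.75	5.04	6
a4b2	frog	ca_permeability	81.51	7.91	6
a4b2	rat	rectification	0.07	0.03	5
a4b2	chicken	rectification	0.03	0.03	6
a4b2	frog	rectification	0.02	0.03	6
a7	rat	EC50	432.1	123.45	8
a7	chicken	EC50	267.56	87.98	8
a7	frog	EC50	239.27	33.90	7
a7	rat	desensitization	3.23	0.79	6
a7	chicken	desensitization	3.18	0.54	9
a7	frog	desensitization	2.00	0.41	6
a7	rat	ca_modulation	0.63	0.10	4
a7	chicken	ca_modulation	0.46	0.06	4
a7	frog	ca_modulation	0.63	0.08	4
a7	rat	ca_permeability	29.07	7.68	4
a7	chicken	ca_permeability	37.10	11.82	4
a7	frog	ca_permeability	38.47	3.98	7
a7	rat	rectification	0.04	0.02	5
a7	chicken	rectification	0.02	0.003	5
a7	frog	rectification	0.03	0.01	5
a9a10	rat	EC50	19.39	2.08	9
a9a10	chicken	EC50	17.62	3.33	6
a9a10	frog	EC50	110.89	25.00	7
a9a10	rat	desensitization	64.46	3.65	5
a9a10	chicken	desensitization	60.84	4.23	9
a9a10	frog	desensitization	14.53	3.01	7
a9a10	rat	ca_modulation	3.76	0.73	5
a9a10	chicken	ca_modulation	1.00	0.07	4
a9a10	frog	ca_modulation	0.63	0.05	12
a9a10	rat	ca_permeability	24.89	2.81	6
a9a10	chicken	ca_permeability	100.28	14.02	6
a9a10	frog	ca_permeability	19.56	3.38	10
a9a10	rat	rectification	1.21	0.07	11
a9a10	chicken	rectification	2.31	0.34	10
a9a10	frog	rectification	0.21	0.05	8
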