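paralog	construct	ca_state	dg_dtt	se_dg_dtt	cmid_dtt	m_dtt	se_m_dtt	dg_gsno	se_dg_gsno	cmid_gsno	m_gsno	se_m_gsno	ddg_printed	ddg_se_printed
STIM2	WT	loaded	6.87	0.02	3.34	2.05	0.11	7.49	0.06	3.58	2.00	0.17	0.62	0.06
STIM2	WT	depleted	4.82	0.02	2.85	1.69	0.08	5.98	0.06	3.11	1.92	0.19	1.16	0.06
STIM2	C15S	depleted	6.22	0.02	3.47	1.78	0.12	6.71	0.02	3.69	1.82	0.27	0.49	0.03
STIM2	C53S/C60S	depleted	3.54	0.01	2.36	1.50	0.07	3.63	0.03	1.47	2.48	0.02	0.10	0.03
STIM2	C15S/C53S/C60S	depleted	3.41	0.17	2.39	1.54	0.17	3.40	0.15	1.58	2.38	0.02	-0.01	0.23
STIM1	WT	loaded	5.91	0.03	3.09	1.91	0.07	7.87	0.15	3.29	2.39	0.06	1.96	0.15
STIM1	WT	depleted	1.73	0.01	1.33	1.30	0.04	3.23	0.06	1.76	1.83	0.06	1.50	0.06
STIM1	C49S/C56S	depleted	1.75	0.03	1.12	1.55	0.11	1.45	0.06	1.15	1.28	0.07	-0.30	0.07
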