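paralog	construct	ca_state	tm_dtt	se_dtt	tm_gsno	se_gsno	dtm_printed	dtm_se_printed
STIM2	WT	loaded	63.2	0.1	67.3	0.7	4.1	0.7
STIM2	C15S	loaded	63.4	0.1	65.8	0.5	2.4	0.5
STIM2	C53S	loaded	63.6	0.1	62.6	0.2	-1.0	0.2
STIM2	C60S	loaded	62.0	0.1	61.0	0.2	-1.0	0.2
STIM2	C53S/C60S	loaded	60.0	0.1	60.1	0.1	0.1	0.1
STIM2	C15S/C53S/C60S	loaded	60.8	0.1	61.2	0.1	0.4	0.1
STIM2	WT	depleted	51.7	0.5	53.4	0.1	1.7	0.5
STIM1	WT	loaded	62.5	0.5	64.3	0.3	1.8	0.6
STIM1	WT	depleted	41.7	0.6	45.1	0.9	3.4	1.1
STIM1	C49S/C56S	depleted	37.9	0.5	37.8	0.4	-0.1	0.6
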