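drug	dose_label	daily_dose_mg	unit	cmax	cmean	ctrough	inr_target
rivaroxaban	5 OD	5	ug_l	60.98	24.28	4.27	NA
rivaroxaban	5 BD	10	ug_l	75.97	42.83	16.36	NA
rivaroxaban	10 OD	10	ug_l	121.97	48.56	8.54	NA
rivaroxaban	10 BD	20	ug_l	151.9	85.66	32.73	NA
rivaroxaban	20 OD	20	ug_l	195.15	77.69	13.66	NA
rivaroxaban	20 BD	40	ug_l	243.1	137.06	52.37	NA
rivaroxaban	53 OD	53	ug_l	387.86	154.42	27.15	NA
rivaroxaban	53 BD	106	ug_l	483.17	272.42	104.08	NA
warfarin	INR 1.5	NA	inr	NA	NA	NA	1.5
warfarin	INR 2	NA	inr	NA	NA	NA	2
warfarin	INR 2.5	NA	inr	NA	NA	NA	2.5
warfarin	INR 3	NA	inr	NA	NA	NA	3
warfarin	INR 3.5	NA	inr	NA	NA	NA	3.5
warfarin	INR 4	NA	inr	NA	NA	NA	4
melagatran	24 BD	48	uM	0.21	0.12	0.04	NA
melagatran	60 BD	120	uM	0.52	0.31	0.12	NA
dx9065a	IV 100	NA	ug_l	100	100	100	NA
dx9065a	IV 200	NA	ug_l	200	200	200	NA
enoxaparin	20 OD	NA	mg_l	1.79	0.76	0.19	NA
enoxaparin	40 OD	NA	mg_l	3.69	1.57	0.4	NA
enoxaparin	30 BD	NA	mg_l	2.74	1.95	0.95	NA
enoxaparin	105 OD (1.5 mg/kg)	NA	mg_l	12.8	5.47	1.4	NA
enoxaparin	70 BD (1 mg/kg)	NA	mg_l	10.79	7.67	3.74	NA
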