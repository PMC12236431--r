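station	campaign	depth_m	compound	replicate_id	concentration	units
67-70	autumn2018	2	B1	1	19.37	pM
67-70	autumn2018	2	B1	2	20.18	pM
67-70	autumn2018	2	B1	3	20.99	pM
67-70	autumn2018	60	B1	1	29.06	pM
67-70	autumn2018	60	B1	2	30.27	pM
67-70	autumn2018	60	B1	3	31.48	pM
67-70	autumn2018	100	B1	1	54.67	pM
67-70	autumn2018	100	B1	2	56.95	pM
67-70	autumn2018	100	B1	3	59.23	pM
67-70	autumn2018	200	B1	1	38.40	pM
67-70	autumn2018	200	B1	2	40.00	pM
67-70	autumn2018	200	B1	3	41.60	pM
67-70	autumn2018	300	B1	1	48.00	pM
67-70	autumn2018	300	B1	2	50.00	pM
67-70	autumn2018	300	B1	3	52.00	pM
67-70	autumn2018	500	B1	1	67.73	pM
67-70	autumn2018	500	B1	2	70.55	pM
67-70	autumn2018	500	B1	3	73.37	pM
67-70	autumn2018	700	B1	1	223.22	pM
67-70	autumn2018	700	B1	2	232.52	pM
67-70	autumn2018	700	B1	3	241.82	pM
67-70	autumn2018	1000	B1	1	69.92	pM
67-70	autumn2018	1000	B1	2	72.83	pM
67-70	autumn2018	1000	B1	3	75.74	pM
67-70	autumn2018	1250	B1	1	91.20	pM
67-70	autumn2018	1250	B1	2	95.00	pM
67-70	autumn2018	1250	B1	3	98.80	pM
67-70	autumn2018	2000	B1	1	36.18	pM
67-70	autumn2018	2000	B1	2	37.69	pM
67-70	autumn2018	2000	B1	3	39.20	pM
67-70	autumn2018	2500	B1	1	10.47	pM
67-70	autumn2018	2500	B1	2	10.91	pM
67-70	autumn2018	2500	B1	3	11.35	pM
67-70	autumn2018	2	AmMP	1	4.43	pM
67-70	autumn2018	2	AmMP	2	4.61	pM
67-70	autumn2018	2	AmMP	3	4.79	pM
67-70	autumn2018	60	AmMP	1	3.68	pM
67-70	autumn2018	60	AmMP	2	3.83	pM
67-70	autumn2018	60	AmMP	3	3.98	pM
67-70	autumn2018	100	AmMP	1	4.80	pM
67-70	autumn2018	100	AmMP	2	5.00	pM
67-70	autumn2018	100	AmMP	3	5.20	pM
67-70	autumn2018	200	AmMP	1	5.76	pM
67-70	autumn2018	200	AmMP	2	6.00	pM
67-70	autumn2018	200	AmMP	3	6.24	pM
67-70	autumn2018	300	AmMP	1	7.20	pM
67-70	autumn2018	300	AmMP	2	7.50	pM
67-70	autumn2018	300	AmMP	3	7.80	pM
67-70	autumn2018	500	AmMP	1	11.52	pM
67-70	autumn2018	500	AmMP	2	12.00	pM
67-70	autumn2018	500	AmMP	3	12.48	pM
67-70	autumn2018	700	AmMP	1	24.35	pM
67-70	autumn2018	700	AmMP	2	25.36	pM
67-70	autumn2018	700	AmMP	3	26.37	pM
67-70	autumn2018	1000	AmMP	1	13.44	pM
67-70	autumn2018	1000	AmMP	2	14.00	pM
67-70	autumn2018	1000	AmMP	3	14.56	pM
67-70	autumn2018	1250	AmMP	1	9.60	pM
67-70	autumn2018	1250	AmMP	2	10.00	pM
67-70	autumn2018	1250	AmMP	3	10.40	pM
67-70	autumn2018	2000	AmMP	1	6.24	pM
67-70	autumn2018	2000	AmMP	2	6.50	pM
67-70	autumn2018	2000	AmMP	3	6.76	pM
67-70	autumn2018	2500	AmMP	1	4.70	pM
67-70	autumn2018	2500	AmMP	2	4.90	pM
67-70	autumn2018	2500	AmMP	3	5.10	pM
67-70	autumn2018	2	HMP	1	0.30	pM
67-70	autumn2018	2	HMP	2	0.31	pM
67-70	autumn2018	2	HMP	3	0.32	pM
67-70	autumn2018	60	HMP	1	0.48	pM
67-70	autumn2018	60	HMP	2	0.50	pM
67-70	autumn2018	60	HMP	3	0.52	pM
67-70	autumn2018	100	HMP	1	0.58	pM
67-70	autumn2018	100	HMP	2	0.60	pM
67-70	autumn2018	100	HMP	3	0.62	pM
67-70	autumn2018	200	HMP	1	0.77	pM
67-70	autumn2018	200	HMP	2	0.80	pM
67-70	autumn2018	200	HMP	3	0.83	pM
67-70	autumn2018	300	HMP	1	0.96	pM
67-70	autumn2018	300	HMP	2	1.00	pM
67-70	autumn2018	300	HMP	3	1.04	pM
67-70	autumn2018	500	HMP	1	1.54	pM
67-70	autumn2018	500	HMP	2	1.60	pM
67-70	autumn2018	500	HMP	3	1.66	pM
67-70	autumn2018	700	HMP	1	3.06	pM
67-70	autumn2018	700	HMP	2	3.19	pM
67-70	autumn2018	700	HMP	3	3.32	pM
67-70	autumn2018	1000	HMP	1	1.44	pM
67-70	autumn2018	1000	HMP	2	1.50	pM
67-70	autumn2018	1000	HMP	3	1.56	pM
67-70	autumn2018	1250	HMP	1	1.15	pM
67-70	autumn2018	1250	HMP	2	1.20	pM
67-70	autumn2018	1250	HMP	3	1.25	pM
67-70	autumn2018	2000	HMP	1	0.67	pM
67-70	autumn2018	2000	HMP	2	0.70	pM
67-70	autumn2018	2000	HMP	3	0.73	pM
67-70	autumn2018	2500	HMP	1	0.38	pM
67-70	autumn2018	2500	HMP	2	0.40	pM
67-70	autumn2018	2500	HMP	3	0.42	pM
67-70	autumn2018	2	HET	1	0.33	pM
67-70	autumn2018	2	HET	2	0.34	pM
67-70	autumn2018	2	HET	3	0.35	pM
67-70	autumn2018	60	HET	1	0.96	pM
67-70	autumn2018	60	HET	2	1.00	pM
67-70	autumn2018	60	HET	3	1.04	pM
67-70	autumn2018	100	HET	1	1.92	pM
67-70	autumn2018	100	HET	2	2.00	pM
67-70	autumn2018	100	HET	3	2.08	pM
67-70	autumn2018	200	HET	1	2.88	pM
67-70	autumn2018	200	HET	2	3.00	pM
67-70	autumn2018	200	HET	3	3.12	pM
67-70	autumn2018	300	HET	1	3.84	pM
67-70	autumn2018	300	HET	2	4.00	pM
67-70	autumn2018	300	HET	3	4.16	pM
67-70	autumn2018	500	HET	1	7.68	pM
67-70	autumn2018	500	HET	2	8.00	pM
67-70	autumn2018	500	HET	3	8.32	pM
67-70	autumn2018	700	HET	1	21.19	pM
67-70	autumn2018	700	HET	2	22.07	pM
67-70	autumn2018	700	HET	3	22.95	pM
67-70	autumn2018	1000	HET	1	8.64	pM
67-70	autumn2018	1000	HET	2	9.00	pM
67-70	autumn2018	1000	HET	3	9.36	pM
67-70	autumn2018	1250	HET	1	5.76	pM
67-70	autumn2018	1250	HET	2	6.00	pM
67-70	autumn2018	1250	HET	3	6.24	pM
67-70	autumn2018	2000	HET	1	2.40	pM
67-70	autumn2018	2000	HET	2	2.50	pM
67-70	autumn2018	2000	HET	3	2.60	pM
67-70	autumn2018	2500	HET	1	0.96	pM
67-70	autumn2018	2500	HET	2	1.00	pM
67-70	autumn2018	2500	HET	3	1.04	pM
67-70	autumn2018	2	cHET	1	2.93	pM
67-70	autumn2018	2	cHET	2	3.05	pM
67-70	autumn2018	2	cHET	3	3.17	pM
67-70	autumn2018	60	cHET	1	4.80	pM
67-70	autumn2018	60	cHET	2	5.00	pM
67-70	autumn2018	60	cHET	3	5.20	pM
67-70	autumn2018	100	cHET	1	7.68	pM
67-70	autumn2018	100	cHET	2	8.00	pM
67-70	autumn2018	100	cHET	3	8.32	pM
67-70	autumn2018	200	cHET	1	9.60	pM
67-70	autumn2018	200	cHET	2	10.00	pM
67-70	autumn2018	200	cHET	3	10.40	pM
67-70	autumn2018	300	cHET	1	11.52	pM
67-70	autumn2018	300	cHET	2	12.00	pM
67-70	autumn2018	300	cHET	3	12.48	pM
67-70	autumn2018	500	cHET	1	17.28	pM
67-70	autumn2018	500	cHET	2	18.00	pM
67-70	autumn2018	500	cHET	3	18.72	pM
67-70	autumn2018	700	cHET	1	28.41	pM
67-70	autumn2018	700	cHET	2	29.59	pM
67-70	autumn2018	700	cHET	3	30.77	pM
67-70	autumn2018	1000	cHET	1	19.20	pM
67-70	autumn2018	1000	cHET	2	20.00	pM
67-70	autumn2018	1000	cHET	3	20.80	pM
67-70	autumn2018	1250	cHET	1	14.40	pM
67-70	autumn2018	1250	cHET	2	15.00	pM
67-70	autumn2018	1250	cHET	3	15.60	pM
67-70	autumn2018	2000	cHET	1	7.68	pM
67-70	autumn2018	2000	cHET	2	8.00	pM
67-70	autumn2018	2000	cHET	3	8.32	pM
67-70	autumn2018	2500	cHET	1	3.84	pM
67-70	autumn2018	2500	cHET	2	4.00	pM
67-70	autumn2018	2500	cHET	3	4.16	pM
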