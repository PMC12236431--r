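station	campaign	depth_m	dissolved_oxygen	nitrite	nitrate	temperature
67-70	autumn2018	2	250	0.05	2	15.2
67-70	autumn2018	60	230	0.1	8	13.8
67-70	autumn2018	100	180	0.2	15	12.1
67-70	autumn2018	200	120	0.5	25	9.5
67-70	autumn2018	300	60	1.2	32	7.8
67-70	autumn2018	500	28	2.5	38	6.1
67-70	autumn2018	700	8	3.1	41	4.9
67-70	autumn2018	1000	25	1.8	43	4
67-70	autumn2018	1250	30	0.9	44	3.4
67-70	autumn2018	2000	80	0.3	45	2.2
67-70	autumn2018	2500	120	0.1	45	1.8
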