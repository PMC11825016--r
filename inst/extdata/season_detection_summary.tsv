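season	total_days	right_detected	humpback_detected	fin_detected	sei_detected	blue_detected
Fall 2017	46	27	14	46	17	3
Winter 2017-2018	90	66	82	90	22	23
Spring 2018	92	55	79	90	81	0
Summer 2018	91	14	88	91	15	0
Fall 2018	91	26	85	91	8	0
Winter 2018-2019	90	68	72	90	2	7
Spring 2019	92	77	88	92	88	0
Summer 2019	92	32	86	92	24	0
Fall 2019	91	17	78	91	7	0
Winter 2019-2020	91	33	64	88	31	17
Spring 2020	92	23	36	92	82	0
Summer 2020	92	15	50	90	16	0
Fall 2020	45	5	43	45	0	0
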