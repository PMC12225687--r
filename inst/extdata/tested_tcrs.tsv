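tcr_id	cdr3_aa	model_score	multimer_pct_1g4	multimer_pct_1g4_c50	multimer_pct_1g4_c53c50	role
1	CASSNTGGVGELFF	2.34	45.8	96.5	95.1	candidate
2	CASSNLGAVGELFF	2.26	0.2	79.5	98.9	candidate
3	CASSYLGVNGELFF	2.23	0.4	93.8	99.3	candidate
4	CASSYVGNNGELFF	2.21	50.9	99.6	99.4	candidate
5	CASSNTGFTGELFF	2.19	39.9	93.7	95.8	candidate
6	CASSYVGHRGELFF	2.15	39.1	99.3	99.5	candidate
7	CASSNLGGLGELFF	2.13	46.8	99.6	99.4	candidate
8	CASSNLGGNGELFF	2.13	8.4	99.4	99.3	candidate
9	CASSNIGTYGELFF	2.12	2.6	65.1	99.0	candidate
10	CASSNTGVLGELFF	2.01	0.0	71.8	94.6	candidate
11	CASSNLGGYEAGELFF	1.69	0.3	0.4	78.8	candidate
12	CASSNLGQLGELFF	1.46	0.7	82.8	99.2	candidate
13	CASSNLGGRAGGELFF	1.31	0.4	9.8	96.0	candidate
14	CASSNLGSGELFF	1.29	2.7	99.3	99.3	candidate
15	CASSNFGNTGELFF	1.26	0.0	83.4	93.2	candidate
16	CASSYLGIRGELFF	1.16	0.3	63.1	99.3	candidate
17	CASSTVGKDGELFF	1.03	0.3	8.5	99.1	candidate
18	CASSYLSGYGGGGELFF	0.73	0.3	2.8	24.0	candidate
19	CASSNGGSHGELFF	0.69	0.0	0.1	85.8	candidate
20	CASSNIAGGLGGGELFF	0.28	0.3	64.9	94.9	candidate
21	CASSGVGNTGELFF	0.27	0.1	36.2	93.6	candidate
22	CASSSLGGGNGGELFF	0.20	0.2	1.4	95.0	candidate
23	CASSGTGHRGELFF	0.05	0.0	0.1	69.5	candidate
24	CASSGLGGIGELFF	-0.03	0.0	10.8	92.8	candidate
25	CASSGTGLGGELFF	-0.17	0.0	0.1	42.7	candidate
26	CASSNLDPGELFF	-0.19	0.2	76.7	99.2	candidate
27	CASSSLGGGQGKGGELFF	-0.20	0.3	0.1	34.9	candidate
28	CASSGLGHGELFF	-0.41	0.0	7.0	75.5	candidate
29	CASSSLSGGPNGGELFF	-1.06	0.2	80.1	99.3	candidate
30	CASSSLSGGAEGGELFF	-1.16	0.3	2.7	87.8	candidate
positive_control	CASSYVGNTGELFF	2.36	90.9	99.6	99.1	positive_control
negative_control	CASSVDTNTGELFF	-1.03	0.0	0.0	0.0	negative_control
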