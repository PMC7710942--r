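# synthetic BLAST outfmt-6 fixture (13th column = qlen); 4 rows pass E<0.001, id>30, cov>0.5
Q1	S1	45.0	80	40	2	1	80	10	89	1e-05	120	100
Q2	S1	30.0	80	52	3	1	80	5	84	1e-05	95	100
Q3	S1	45.0	50	25	1	1	50	20	69	1e-05	88	100
Q4	S1	45.0	80	40	2	1	80	10	89	0.001	70	100
Q5	S2	90.0	100	10	0	1	100	1	100	1e-100	480	100
Q6	S2	30.1	51	33	2	1	51	7	57	9e-04	52	100
Q7	S2	29.9	99	65	4	1	99	2	100	1e-10	110	100
Q8	S3	80.0	40	8	0	1	40	1	40	1e-20	130	100
Q9	S3	55.0	60	25	2	1	60	11	70	0.01	60	100
Q10	S3	60.0	75	28	1	1	75	6	80	1e-08	140	100
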