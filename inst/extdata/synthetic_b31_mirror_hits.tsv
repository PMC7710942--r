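# synthetic hit file linking the first four mirror candidates to known-family subjects (13th column = qlen)
SIM00001	AT_MLS_A	52.5	300	130	5	1	300	1	300	1e-80	550	320
SIM00002	AT_PKT_A	48.0	250	120	4	1	250	1	250	1e-60	420	280
SIM00003	AT_TTL_A	41.2	180	95	3	1	180	10	189	1e-40	300	210
SIM00004	AT_HIT_A	37.5	140	80	2	1	140	1	140	1e-25	190	160
SIM00005	NR_HYPO_77	55.0	200	85	2	1	200	1	200	1e-50	350	240
SIM00006	AT_MLS_A	25.0	310	210	9	1	310	1	310	1e-30	220	330
SIM00007	AT_PKT_A	45.0	90	45	2	1	90	1	90	1e-20	150	260
SIM00009	NR_HYPO_12	62.0	150	50	1	1	150	1	150	1e-45	280	170
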