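kind	protein	start	peptide	cys_offset
pts2_in_window	1	10	RIDSLGQHL	
pts2_in_window	2	12	RLDSLGQHL	
pts2_in_window	3	12	RLDSLGQHL	
pts2_in_window	4	4	RLDSLGQHL	
pts2_in_window	5	35	RLDSLGQQL	
pts2_in_window	6	24	KLDSLGQQL	
pts2_in_window	7	16	RIDSLGQHL	
pts2_in_window	8	19	RVDSLGQHA	
pts2_in_window	9	29	RLDSLGQQA	
pts2_in_window	10	2	KLDSLGQQL	
pts2_in_window	11	10	KVDSLGQHA	
pts2_in_window	12	20	RLDSLGQQL	
pts2_in_window	13	6	RLDSLGQHL	
pts1_tail	5		SRL	
pts2_out_of_window	14	60	RLDSLGQHL	
pts2_out_of_window	15	60	RLDSLGQHL	
pts2_out_of_window	16	60	RLDSLGQHL	
pts2_out_of_window	17	60	RLDSLGQHL	
pts2_out_of_window	18	60	RLDSLGQHL	
pts2_out_of_window	19	60	RLDSLGQHL	
pts2_out_of_window	20	60	RLDSLGQHL	
pts2_out_of_window	21	60	RLDSLGQHL	
pts2_out_of_window	22	60	RLDSLGQHL	
pts2_out_of_window	23	60	RLDSLGQHL	
pts2_out_of_window	24	60	RLDSLGQHL	
pts2_out_of_window	25	60	RLDSLGQHL	
pts2_out_of_window	26	60	RLDSLGQHL	
pts2_out_of_window	27	60	RLDSLGQHL	
pts2_out_of_window	28	60	RLDSLGQHL	
pts2_out_of_window	29	60	RLDSLGQHL	
pts2_out_of_window	30	60	RLDSLGQHL	
pts2_out_of_window	31	60	RLDSLGQHL	
pts2_out_of_window	32	60	RLDSLGQHL	
pts2_out_of_window	33	60	RLDSLGQHL	
pts2_out_of_window	34	60	RLDSLGQHL	
pts2_out_of_window	35	60	RLDSLGQHL	
pts2_out_of_window	36	60	RLDSLGQHL	
pts2_out_of_window	37	60	RLDSLGQHL	
pts2_out_of_window	38	60	RLDSLGQHL	
pts2_out_of_window	39	60	RLDSLGQHL	
pts2_out_of_window	40	60	RLDSLGQHL	
pts2_out_of_window	41	60	RLDSLGQHL	
pts2_out_of_window	42	60	RLDSLGQHL	
pts2_out_of_window	43	60	RLDSLGQHL	
pts2_out_of_window	44	60	RLDSLGQHL	
pts2_out_of_window	45	60	RLDSLGQHL	
pts2_out_of_window	46	60	RLDSLGQHL	
pts2_out_of_window	47	60	RLDSLGQHL	
pts2_out_of_window	48	60	RLDSLGQHL	
pts2_out_of_window	49	60	RLDSLGQHL	
pts2_out_of_window	50	60	RLDSLGQHL	
pts2_out_of_window	51	60	RLDSLGQHL	
broken_pts2	52	10	RLDSLGQRG	
broken_pts2	53	10	RLDSLGQRG	
broken_pts2	54	10	RLDSLGQRG	
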