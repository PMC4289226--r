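toxin_set	n_seqs	m0_omega	neg_lnL_null	neg_lnL_alt	p_printed
SVMP-MP	18	1.15	4097.97	4036.79	2.7e-27
SVMP-DIS	18	1.29	1389.94	1357.74	1.0e-14
SVMP-ACR	18	1.39	2197.91	2133.66	1.2e-28
3FTx	11	1.78	1300.92	1269.86	3.2e-14
CTL	12	0.53	3913.45	3892.88	1.2e-9
Ficolin	7	0.37	4468.63	4456.99	8.8e-6
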