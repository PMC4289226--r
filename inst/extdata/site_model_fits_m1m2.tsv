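toxin_set	n_seqs	m0_omega	neg_lnL_null	neg_lnL_alt	p_printed
SVMP-MP	18	1.15	4092.28	4035.46	2.1e-25
SVMP-DIS	18	1.29	1388.59	1357.60	3.5e-14
SVMP-ACR	18	1.39	2196.52	2133.51	4.3e-28
3FTx	11	1.78	1300.12	1269.82	6.9e-14
CTL	12	0.53	3921.91	3902.58	4.0e-9
Ficolin	7	0.37	4470.30	4458.24	5.8e-6
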