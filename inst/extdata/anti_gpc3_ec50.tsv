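# humanized anti-GPC3 YP9.1 panel: EC50 vs reported wRMSD
candidate_id	wrmsd	measure	value	units	censored
YP9.1	1.995	EC50	1.8	nM	FALSE
hYP9.1a	2.239	EC50	47.0	nM	FALSE
hYP9.1b	2.092	EC50	6.7	nM	FALSE
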