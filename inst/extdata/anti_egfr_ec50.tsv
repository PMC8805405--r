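# humanized anti-EGFR a4.6.1 panel: EC50 vs reported wRMSD
candidate_id	wrmsd	measure	value	units	censored
fab8	3.140	EC50	0.470	nM	FALSE
fab10	3.118	EC50	0.314	nM	FALSE
fab11	3.066	EC50	0.162	nM	FALSE
fab12	2.997	EC50	0.078	nM	FALSE
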