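# humanized anti-a4b1-integrin HP1/2L panel: EC50 vs reported wRMSD
candidate_id	wrmsd	measure	value	units	censored
HP1/2L	2.116	EC50	0.015	nM	FALSE
v143	3.080	EC50	0.53	nM	FALSE
v144	2.508	EC50	0.038	nM	FALSE
v152	2.484	EC50	0.023	nM	FALSE
v208	2.787	EC50	0.3	nM	FALSE
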