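# humanized anti-TNF-alpha panel: ELISA EC50 vs reported wRMSD; C5 censored (> 1000)
candidate_id	wrmsd	measure	value	units	censored
rRemicade	1.137	EC50	19.03	ng/mL	FALSE
C1	1.207	EC50	25.83	ng/mL	FALSE
C2	1.214	EC50	26.08	ng/mL	FALSE
C3	1.327	EC50	513.65	ng/mL	FALSE
C4	1.400	EC50	545.70	ng/mL	FALSE
C5	1.469	EC50	1000	ng/mL	TRUE
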