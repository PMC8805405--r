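# humanized anti-TNF-alpha panel: biolayer-interferometry KD vs reported wRMSD
candidate_id	wrmsd	measure	value	units	censored
rRemicade	1.137	KD	5.13e-10	M	FALSE
C1	1.207	KD	9.35e-10	M	FALSE
C3	1.327	KD	5.50e-9	M	FALSE
C5	1.469	KD	1.77e-8	M	FALSE
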