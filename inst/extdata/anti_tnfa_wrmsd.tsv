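# literature-reported wRMSD of humanized anti-TNF-alpha candidates (Angstrom)
candidate_id	wrmsd
C1 (A + a)	1.207
C2 (A + b)	1.214
B + c	1.308
C3 (B + b)	1.327
C4 (B + a)	1.400
A + c	1.452
C + c	1.453
C + a	1.465
C5 (C + b)	1.469
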