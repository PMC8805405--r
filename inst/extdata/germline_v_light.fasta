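>IGKVT1*01 synthetic toy light V segment
DIQMTQTPSSLSASVGDRVTITCRASQSISSYLNWYQQKPSKAPKLLIYAASSLQSGVPSRFSGSRSGTDFTLTISSLQPEDFATYYCQQS
>IGKVT2*01 synthetic toy light V segment
EIQMTQTPSSLSASVGDRVTITCKASQNVGTNVAWYQQKPSKAPKLLVYSASYRYSGVASKFSGSRSGTDFTLTISSLQPEDFATYYCQQY
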