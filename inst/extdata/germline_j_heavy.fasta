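>JHT5 synthetic toy heavy J segment
YWGQGTLVTVSS
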