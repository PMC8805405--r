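>IGHVT1*01 synthetic toy heavy V segment
EVQLVESGGGLLQPGGSLRLCAASGFNIKSYAMHWVRQAPGKGLEWVAVISYDGSNKYYADSVKGRFTISGDDSKNTLYLQMNSLKTEDTAVYYTACAKAR
>IGHVT2*01 synthetic toy heavy V segment
EVKLVESGGGLLQPGGSLRLCAASGFNIKNYGMNWVRQPPGKGLEWVAYISSGSSTIYYADTVKGRFTISGDDSKNTLYLEMNSLKTEDTAIYYTACAKAK
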