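primaryid$outc_cod
1000011$HO
1000021$OT
1000031$OT
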