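primaryid$pt
1000011$Tubulointerstitial nephritis
1000011$Rash
1000021$Nausea
1000031$Myalgia
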