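primaryid$drug_seq$role_cod$drugname$prod_ai
1000011$1$PS$CRESTOR$ROSUVASTATIN CALCIUM
1000011$2$C$ASPIRIN$ASPIRIN
1000021$1$PS$METFORMIN$METFORMIN HYDROCHLORIDE
1000031$1$PS$LIPITOR$
1000031$2$SS$DRUG001$DRUG001 AI
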