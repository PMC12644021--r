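# Statin name lexicon: token<TAB>canonical ingredient.
# Matching is case-insensitive on word-boundary tokens; edit or extend at will.
rosuvastatin	rosuvastatin
crestor	rosuvastatin
ezallor	rosuvastatin
atorvastatin	atorvastatin
lipitor	atorvastatin
caduet	atorvastatin
simvastatin	simvastatin
zocor	simvastatin
vytorin	simvastatin
pravastatin	pravastatin
pravachol	pravastatin
pitavastatin	pitavastatin
livalo	pitavastatin
lovastatin	lovastatin
mevacor	lovastatin
altoprev	lovastatin
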