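primaryid$caseid$caseversion$event_dt$fda_dt$sex$age$age_cod$occ_cod$occr_country$reporter_country
1000011$100001$1$20240105$20240110$F$72$YR$MD$US$US
1000021$100002$1$202402$20240215$M$6$DEC$OT$FR$FR
1000031$100003$1$$20240320$UNK$45$YR$CN$$GB
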