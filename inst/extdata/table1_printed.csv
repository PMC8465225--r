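"row","col","printed","status","note"
"A0","1",2.75,"verified",""
"A0","12.5",3.024,"verified",""
"A0","25",3.1,"verified",""
"A0","125",3.274,"verified",""
"A0","225",3.38,"typo-suspect","printed 3.38; formula gives 3.338 (likely dropped digit)"
"A0","525",3.43,"verified",""
"A0","1000",3.5,"verified",""
"A0","10000",3.75,"verified",""
"A0","20000",4.9,"typo-suspect","printed 4.900; formula gives 3.825"
"nu","1",0.794,"verified",""
"nu","12.5",0.72,"verified",""
"nu","25",0.7,"verified",""
"nu","125",0.653,"verified",""
"nu","225",0.636,"verified",""
"nu","525",0.607,"paper-drift",""
"nu","1000",0.592,"verified",""
"nu","10000",0.524,"verified",""
"nu","20000",0.504,"verified",""
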