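"row","col","printed","status","note"
"20","DS",3.3,"verified",""
"20","R",2.71,"verified",""
"20","SS",4.7,"paper-drift","sparse-sphere construction under-specified; treated as approximate"
"20","Pa",3.5,"verified",""
"20","SR",11.53,"verified",""
"20","Ring",3.2,"verified",""
"30","DS",3.8,"verified",""
"30","R",3.11,"verified",""
"30","SS",5.2,"paper-drift","sparse-sphere construction under-specified; treated as approximate"
"30","Pa",4.5,"paper-drift","parabola construction under-specified; treated as approximate"
"30","SR",17.31,"verified",""
"30","Ring",4.8,"verified",""
"40","DS",4.5,"verified",""
"40","R",3.42,"verified",""
"40","SS",6.3,"paper-drift","sparse-sphere construction under-specified; treated as approximate"
"40","Pa",5.4,"paper-drift","parabola construction under-specified; treated as approximate"
"40","SR",23.08,"verified",""
"40","Ring",6.4,"verified",""
"50","DS",4.9,"typo-suspect","printed 4.9 matches the volume-ratio capacity sequence, not the 1/7/19/37 shells (4.82)"
"50","R",3.68,"verified",""
"50","SS",6.6,"paper-drift","sparse-sphere construction under-specified; treated as approximate"
"50","Pa",6.7,"paper-drift","parabola construction under-specified; treated as approximate"
"50","SR",28.86,"verified",""
"50","Ring",8,"verified",""
"60","DS",5.3,"paper-drift",""
"60","R",3.91,"verified",""
"60","SS",9.6,"typo-suspect","printed 9.6 jumps off the SS trend; dilated-shell construction gives 6.3"
"60","Pa",7,"paper-drift","parabola construction under-specified; treated as approximate"
"60","SR",34.63,"verified",""
"60","Ring",9.5,"verified",""
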