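"row","col","printed","status","note"
"20","1",2.4,"verified",""
"20","2",3.2,"verified",""
"20","3",3.6,"verified",""
"20","4",4,"verified",""
"20","5",4.2,"verified",""
"20","N/10",3.2,"verified",""
"20","N/5",4,"verified",""
"20","N/2",5,"paper-drift",""
"20","N",5.3,"verified",""
"30","1",3,"verified",""
"30","2",4.1,"verified",""
"30","3",4.8,"verified",""
"30","4",5.3,"verified",""
"30","5",5.7,"verified",""
"30","N/10",4.8,"verified",""
"30","N/5",6,"verified",""
"30","N/2",7.3,"verified",""
"30","N",8,"paper-drift",""
"40","1",3.5,"verified",""
"40","2",4.8,"verified",""
"40","3",5.7,"verified",""
"40","4",6.3,"verified",""
"40","5",6.9,"verified",""
"40","N/10",6.3,"verified",""
"40","N/5",7.9,"verified",""
"40","N/2",9.7,"verified",""
"40","N",10.5,"verified",""
"50","1",4,"verified",""
"50","2",5.4,"verified",""
"50","3",6.5,"verified",""
"50","4",7.3,"verified",""
"50","5",7.9,"verified",""
"50","N/10",7.9,"verified",""
"50","N/5",9.9,"verified",""
"50","N/2",12,"paper-drift",""
"50","N",13.1,"verified",""
"60","1",4.4,"verified",""
"60","2",6,"verified",""
"60","3",7.2,"verified",""
"60","4",8.1,"verified",""
"60","5",8.9,"verified",""
"60","N/10",9.5,"verified",""
"60","N/5",11.9,"verified",""
"60","N/2",14.5,"verified",""
"60","N",13.8,"typo-suspect","printed 13.8 < the Lp=N/2 cell; formula gives 15.77"
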