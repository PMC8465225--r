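"row","col","printed","status","note"
"Rg|12.5","20",8.8,"paper-drift","printed value not reproduced by N^nu with the printed nu"
"Rg|12.5","30",11.7,"paper-drift","printed value not reproduced by N^nu with the printed nu"
"Rg|12.5","40",14.5,"paper-drift","printed value not reproduced by N^nu with the printed nu"
"Rg|12.5","50",17,"paper-drift","printed value not reproduced by N^nu with the printed nu"
"Rg|12.5","60",19.4,"paper-drift","printed value not reproduced by N^nu with the printed nu"
"Rg|25","20",7.9,"paper-drift","printed value not reproduced by N^nu with the printed nu"
"Rg|25","30",10.5,"paper-drift","printed value not reproduced by N^nu with the printed nu"
"Rg|25","40",12.8,"paper-drift","printed value not reproduced by N^nu with the printed nu"
"Rg|25","50",14.9,"paper-drift","printed value not reproduced by N^nu with the printed nu"
"Rg|25","60",16.9,"paper-drift","printed value not reproduced by N^nu with the printed nu"
"Rg|125","20",7.1,"verified",""
"Rg|125","30",9.2,"verified",""
"Rg|125","40",11.1,"verified",""
"Rg|125","50",12.8,"verified",""
"Rg|125","60",14.4,"verified",""
"Rg|225","20",6.5,"paper-drift","printed value not reproduced by N^nu with the printed nu"
"Rg|225","30",8.4,"paper-drift","printed value not reproduced by N^nu with the printed nu"
"Rg|225","40",10,"paper-drift","printed value not reproduced by N^nu with the printed nu"
"Rg|225","50",11.5,"paper-drift","printed value not reproduced by N^nu with the printed nu"
"Rg|225","60",12.9,"paper-drift","printed value not reproduced by N^nu with the printed nu"
"Rg|525","20",6.2,"verified",""
"Rg|525","30",8,"verified",""
"Rg|525","40",9.5,"verified",""
"Rg|525","50",11,"verified",""
"Rg|525","60",12,"paper-drift","printed value not reproduced by N^nu with the printed nu"
"Rh|12.5","20",3.8,"verified",""
"Rh|12.5","30",4.4,"verified",""
"Rh|12.5","40",4.9,"verified",""
"Rh|12.5","50",5.3,"verified",""
"Rh|12.5","60",5.7,"verified",""
"Rh|25","20",3.6,"verified",""
"Rh|25","30",4.2,"verified",""
"Rh|25","40",4.6,"verified",""
"Rh|25","50",5,"verified",""
"Rh|25","60",5.3,"paper-drift","chained by the source from its drifted printed Rg"
"Rh|125","20",3.4,"verified",""
"Rh|125","30",3.9,"verified",""
"Rh|125","40",4.3,"verified",""
"Rh|125","50",4.6,"verified",""
"Rh|125","60",4.9,"verified",""
"Rh|225","20",3.3,"verified",""
"Rh|225","30",3.7,"paper-drift","chained by the source from its drifted printed Rg"
"Rh|225","40",4.1,"verified",""
"Rh|225","50",4.4,"verified",""
"Rh|225","60",4.6,"paper-drift","chained by the source from its drifted printed Rg"
"Rh|525","20",3.2,"verified",""
"Rh|525","30",3.6,"verified",""
"Rh|525","40",4,"verified",""
"Rh|525","50",4.3,"verified",""
"Rh|525","60",4.5,"verified",""
"Ree|12.5","20",11.8,"verified",""
"Ree|12.5","30",13.7,"verified",""
"Ree|12.5","40",15.2,"verified",""
"Ree|12.5","50",16.5,"paper-drift","chained by the source from its drifted printed Rg"
"Ree|12.5","60",16.6,"typo-suspect","printed 16.6 inconsistent with 3.1*Rh of its own Rh row"
"Ree|25","20",11.3,"paper-drift","chained by the source from its drifted printed Rg"
"Ree|25","30",13,"paper-drift","chained by the source from its drifted printed Rg"
"Ree|25","40",14.3,"paper-drift","chained by the source from its drifted printed Rg"
"Ree|25","50",15.5,"paper-drift","chained by the source from its drifted printed Rg"
"Ree|25","60",16.5,"paper-drift","chained by the source from its drifted printed Rg"
"Ree|125","20",10.6,"verified",""
"Ree|125","30",12.1,"verified",""
"Ree|125","40",13.3,"verified",""
"Ree|125","50",14.3,"verified",""
"Ree|125","60",15.2,"verified",""
"Ree|225","20",10.2,"paper-drift","chained by the source from its drifted printed Rg"
"Ree|225","30",11.6,"paper-drift","chained by the source from its drifted printed Rg"
"Ree|225","40",12.7,"paper-drift","chained by the source from its drifted printed Rg"
"Ree|225","50",13.6,"paper-drift","chained by the source from its drifted printed Rg"
"Ree|225","60",14.4,"paper-drift","chained by the source from its drifted printed Rg"
"Ree|525","20",10,"verified",""
"Ree|525","30",11.3,"verified",""
"Ree|525","40",12.3,"verified",""
"Ree|525","50",13.2,"verified",""
"Ree|525","60",14,"verified",""
"R","20",2.7,"verified",""
"R","30",3.1,"verified",""
"R","40",3.4,"verified",""
"R","50",3.7,"verified",""
"R","60",3.9,"verified",""
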