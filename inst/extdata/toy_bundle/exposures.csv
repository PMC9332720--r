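"factor_id","sex","age_start","mean","sd","category","prevalence"
"smoke","male",0,NA,NA,"unexposed",0.8
"smoke","female",0,NA,NA,"unexposed",0.8
"smoke","male",1,NA,NA,"unexposed",0.8
"smoke","female",1,NA,NA,"unexposed",0.8
"smoke","male",5,NA,NA,"unexposed",0.8
"smoke","female",5,NA,NA,"unexposed",0.8
"smoke","male",10,NA,NA,"unexposed",0.8
"smoke","female",10,NA,NA,"unexposed",0.8
"smoke","male",15,NA,NA,"unexposed",0.8
"smoke","female",15,NA,NA,"unexposed",0.8
"smoke","male",20,NA,NA,"unexposed",0.8
"smoke","female",20,NA,NA,"unexposed",0.8
"smoke","male",25,NA,NA,"unexposed",0.8
"smoke","female",25,NA,NA,"unexposed",0.8
"smoke","male",30,NA,NA,"unexposed",0.8
"smoke","female",30,NA,NA,"unexposed",0.8
"smoke","male",35,NA,NA,"unexposed",0.8
"smoke","female",35,NA,NA,"unexposed",0.8
"smoke","male",40,NA,NA,"unexposed",0.8
"smoke","female",40,NA,NA,"unexposed",0.8
"smoke","male",45,NA,NA,"unexposed",0.8
"smoke","female",45,NA,NA,"unexposed",0.8
"smoke","male",50,NA,NA,"unexposed",0.8
"smoke","female",50,NA,NA,"unexposed",0.8
"smoke","male",55,NA,NA,"unexposed",0.8
"smoke","female",55,NA,NA,"unexposed",0.8
"smoke","male",60,NA,NA,"unexposed",0.8
"smoke","female",60,NA,NA,"unexposed",0.8
"smoke","male",65,NA,NA,"unexposed",0.8
"smoke","female",65,NA,NA,"unexposed",0.8
"smoke","male",70,NA,NA,"unexposed",0.8
"smoke","female",70,NA,NA,"unexposed",0.8
"smoke","male",75,NA,NA,"unexposed",0.8
"smoke","female",75,NA,NA,"unexposed",0.8
"smoke","male",80,NA,NA,"unexposed",0.8
"smoke","female",80,NA,NA,"unexposed",0.8
"smoke","male",85,NA,NA,"unexposed",0.8
"smoke","female",85,NA,NA,"unexposed",0.8
"smoke","male",90,NA,NA,"unexposed",0.8
"smoke","female",90,NA,NA,"unexposed",0.8
"smoke","male",95,NA,NA,"unexposed",0.8
"smoke","female",95,NA,NA,"unexposed",0.8
"smoke","male",0,NA,NA,"exposed",0.2
"smoke","female",0,NA,NA,"exposed",0.2
"smoke","male",1,NA,NA,"exposed",0.2
"smoke","female",1,NA,NA,"exposed",0.2
"smoke","male",5,NA,NA,"exposed",0.2
"smoke","female",5,NA,NA,"exposed",0.2
"smoke","male",10,NA,NA,"exposed",0.2
"smoke","female",10,NA,NA,"exposed",0.2
"smoke","male",15,NA,NA,"exposed",0.2
"smoke","female",15,NA,NA,"exposed",0.2
"smoke","male",20,NA,NA,"exposed",0.2
"smoke","female",20,NA,NA,"exposed",0.2
"smoke","male",25,NA,NA,"exposed",0.2
"smoke","female",25,NA,NA,"exposed",0.2
"smoke","male",30,NA,NA,"exposed",0.2
"smoke","female",30,NA,NA,"exposed",0.2
"smoke","male",35,NA,NA,"exposed",0.2
"smoke","female",35,NA,NA,"exposed",0.2
"smoke","male",40,NA,NA,"exposed",0.2
"smoke","female",40,NA,NA,"exposed",0.2
"smoke","male",45,NA,NA,"exposed",0.2
"smoke","female",45,NA,NA,"exposed",0.2
"smoke","male",50,NA,NA,"exposed",0.2
"smoke","female",50,NA,NA,"exposed",0.2
"smoke","male",55,NA,NA,"exposed",0.2
"smoke","female",55,NA,NA,"exposed",0.2
"smoke","male",60,NA,NA,"exposed",0.2
"smoke","female",60,NA,NA,"exposed",0.2
"smoke","male",65,NA,NA,"exposed",0.2
"smoke","female",65,NA,NA,"exposed",0.2
"smoke","male",70,NA,NA,"exposed",0.2
"smoke","female",70,NA,NA,"exposed",0.2
"smoke","male",75,NA,NA,"exposed",0.2
"smoke","female",75,NA,NA,"exposed",0.2
"smoke","male",80,NA,NA,"exposed",0.2
"smoke","female",80,NA,NA,"exposed",0.2
"smoke","male",85,NA,NA,"exposed",0.2
"smoke","female",85,NA,NA,"exposed",0.2
"smoke","male",90,NA,NA,"exposed",0.2
"smoke","female",90,NA,NA,"exposed",0.2
"smoke","male",95,NA,NA,"exposed",0.2
"smoke","female",95,NA,NA,"exposed",0.2
"sbp","male",0,125,15,NA,NA
"sbp","female",0,125,15,NA,NA
"sbp","male",1,125,15,NA,NA
"sbp","female",1,125,15,NA,NA
"sbp","male",5,125,15,NA,NA
"sbp","female",5,125,15,NA,NA
"sbp","male",10,125,15,NA,NA
"sbp","female",10,125,15,NA,NA
"sbp","male",15,125,15,NA,NA
"sbp","female",15,125,15,NA,NA
"sbp","male",20,125,15,NA,NA
"sbp","female",20,125,15,NA,NA
"sbp","male",25,125,15,NA,NA
"sbp","female",25,125,15,NA,NA
"sbp","male",30,125,15,NA,NA
"sbp","female",30,125,15,NA,NA
"sbp","male",35,125,15,NA,NA
"sbp","female",35,125,15,NA,NA
"sbp","male",40,125,15,NA,NA
"sbp","female",40,125,15,NA,NA
"sbp","male",45,125,15,NA,NA
"sbp","female",45,125,15,NA,NA
"sbp","male",50,125,15,NA,NA
"sbp","female",50,125,15,NA,NA
"sbp","male",55,125,15,NA,NA
"sbp","female",55,125,15,NA,NA
"sbp","male",60,125,15,NA,NA
"sbp","female",60,125,15,NA,NA
"sbp","male",65,125,15,NA,NA
"sbp","female",65,125,15,NA,NA
"sbp","male",70,125,15,NA,NA
"sbp","female",70,125,15,NA,NA
"sbp","male",75,125,15,NA,NA
"sbp","female",75,125,15,NA,NA
"sbp","male",80,125,15,NA,NA
"sbp","female",80,125,15,NA,NA
"sbp","male",85,125,15,NA,NA
"sbp","female",85,125,15,NA,NA
"sbp","male",90,125,15,NA,NA
"sbp","female",90,125,15,NA,NA
"sbp","male",95,125,15,NA,NA
"sbp","female",95,125,15,NA,NA
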