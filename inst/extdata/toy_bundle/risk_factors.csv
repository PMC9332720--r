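"factor_id","name","kind","units","tmrel","categories","applicable_sexes","age_min","age_max","support_min","support_max"
"smoke","smoking status","categorical","","unexposed","unexposed|exposed","male|female",0,150,-Inf,Inf
"sbp","systolic blood pressure","continuous","mmHg","110","","male|female",0,150,80,250
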