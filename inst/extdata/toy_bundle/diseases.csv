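"disease_id","name","cause_group","is_residual"
"d_cvd","cardiovascular disease","cvd",FALSE
"d_cancer","cancer","cancer",FALSE
"resid","residual causes","other",TRUE
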