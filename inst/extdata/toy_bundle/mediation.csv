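"factor_id","mediator_id","disease_id","mf"
"smoke","sbp","d_cvd",0.5
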