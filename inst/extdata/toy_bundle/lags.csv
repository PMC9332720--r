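"factor_id","disease_id","half_life_years"
"smoke","d_cvd",5
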