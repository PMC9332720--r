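"factor_id","disease_id","sex","age_start","form","params_json"
"smoke","d_cvd","male",0,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","female",0,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","male",1,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","female",1,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","male",5,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","female",5,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","male",10,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","female",10,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","male",15,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","female",15,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","male",20,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","female",20,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","male",25,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","female",25,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","male",30,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","female",30,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","male",35,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","female",35,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","male",40,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","female",40,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","male",45,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","female",45,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","male",50,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","female",50,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","male",55,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","female",55,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","male",60,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","female",60,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","male",65,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","female",65,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","male",70,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","female",70,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","male",75,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","female",75,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","male",80,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","female",80,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","male",85,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","female",85,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","male",90,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","female",90,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","male",95,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"smoke","d_cvd","female",95,"categorical","{""rr"":{""unexposed"":1,""exposed"":2}}"
"sbp","d_cvd","male",0,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","female",0,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","male",1,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","female",1,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","male",5,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","female",5,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","male",10,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","female",10,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","male",15,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","female",15,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","male",20,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","female",20,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","male",25,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","female",25,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","male",30,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","female",30,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","male",35,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","female",35,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","male",40,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","female",40,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","male",45,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","female",45,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","male",50,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","female",50,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","male",55,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","female",55,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","male",60,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","female",60,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","male",65,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","female",65,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","male",70,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","female",70,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","male",75,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","female",75,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","male",80,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","female",80,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","male",85,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","female",85,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","male",90,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","female",90,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","male",95,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
"sbp","d_cvd","female",95,"loglinear","{""beta_above"":0.0202732554054082,""beta_below"":0}"
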