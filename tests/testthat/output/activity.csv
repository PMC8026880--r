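"fly_id","group","bin_start","value","n_defined"
"fly00","pre-fed",0,0.4,30
"fly00","pre-fed",30,0.633333333333333,30
"fly00","pre-fed",60,0.666666666666667,30
"fly01","pre-starved",0,0.1,30
"fly01","pre-starved",30,0.0666666666666667,30
"fly01","pre-starved",60,0.1,30
"fly02","pre-fed",0,0.866666666666667,30
"fly02","pre-fed",30,0.433333333333333,30
"fly02","pre-fed",60,0.6,30
"fly03","pre-starved",0,0,30
"fly03","pre-starved",30,0.166666666666667,30
"fly03","pre-starved",60,0.1,30
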