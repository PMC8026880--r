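"fly_id","group","bin_start","value","n_defined"
"fly00","pre-fed",0,0.0333333333333333,60
"fly00","pre-fed",60,0.0333333333333333,60
"fly01","pre-starved",0,0.25,60
"fly01","pre-starved",60,0.433333333333333,60
"fly02","pre-fed",0,0,60
"fly02","pre-fed",60,0.0166666666666667,60
"fly03","pre-starved",0,0.516666666666667,60
"fly03","pre-starved",60,0.6,60
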