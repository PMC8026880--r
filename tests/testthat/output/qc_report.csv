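"fly_id","sector","group","missing_rate","n_jumps","excluded"
"fly00",0,"pre-fed",0.291666666666667,1,TRUE
"fly01",1,"pre-starved",0.266666666666667,0,TRUE
"fly02",2,"pre-fed",0.275,1,TRUE
"fly03",3,"pre-starved",0.241666666666667,0,TRUE
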