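"fly_id","group","k","duration_range","count"
"fly00","pre-fed",1,"2-3 s",4
"fly00","pre-fed",2,"4-7 s",4
"fly00","pre-fed",3,"8-15 s",1
"fly00","pre-fed",4,"16-31 s",0
"fly00","pre-fed",5,"32-63 s",0
"fly00","pre-fed",6,"64-127 s",0
"fly01","pre-starved",1,"2-3 s",2
"fly01","pre-starved",2,"4-7 s",3
"fly01","pre-starved",3,"8-15 s",3
"fly01","pre-starved",4,"16-31 s",2
"fly01","pre-starved",5,"32-63 s",0
"fly01","pre-starved",6,"64-127 s",0
"fly02","pre-fed",1,"2-3 s",2
"fly02","pre-fed",2,"4-7 s",4
"fly02","pre-fed",3,"8-15 s",1
"fly02","pre-fed",4,"16-31 s",0
"fly02","pre-fed",5,"32-63 s",0
"fly02","pre-fed",6,"64-127 s",0
"fly03","pre-starved",1,"2-3 s",1
"fly03","pre-starved",2,"4-7 s",3
"fly03","pre-starved",3,"8-15 s",3
"fly03","pre-starved",4,"16-31 s",1
"fly03","pre-starved",5,"32-63 s",1
"fly03","pre-starved",6,"64-127 s",0
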