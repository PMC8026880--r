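"fly_id","group","short","long","n_moving"
"fly00","pre-fed",0.028169014084507,0.197183098591549,71
"fly01","pre-starved",0.722222222222222,0,18
"fly02","pre-fed",0.0632911392405063,0.20253164556962,79
"fly03","pre-starved",0.692307692307692,0,13
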