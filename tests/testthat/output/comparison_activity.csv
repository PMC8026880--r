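"bin_start","U","p","n_a","n_b","testable","significant"
0,0,0.333333333333333,2,2,TRUE,FALSE
30,0,0.333333333333333,2,2,TRUE,FALSE
60,0,0.220671361919847,2,2,TRUE,FALSE
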