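position,res,atom,ppm,synthetic
2,C,CB,28.13,FALSE
3,C,CB,38.84,FALSE
7,C,CB,28.12,FALSE
13,C,CB,42.07,FALSE
4,T,CB,69.5,TRUE
8,D,CB,41.0,TRUE
10,T,CB,69.8,TRUE
14,T,CB,69.2,TRUE
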