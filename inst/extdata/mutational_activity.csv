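variant_id,substitutions,redox_state,concentration,mga_ratio
pep8_ox,,oxidized,0.25,0.85
pep8_ox,,oxidized,0.5,0.45
pep8_ox,,oxidized,1,0.12
pep8_ox,,oxidized,2,0.08
pep8_red,,reduced,1,0.98
T4S,T4S,oxidized,1,0.18
T10S,T10S,oxidized,1,1.02
T14S,T14S,oxidized,1,0.97
D8S,D8S,oxidized,1,1.05
T_all_S,T4S;T10S;T14S,oxidized,1,1.01
C3S_C13S,C3S;C13S,oxidized,1,0.99
C2S_C7S,C2S;C7S,oxidized,1,0.22
scramble,T4D;D8T;T10C;C13T,oxidized,1,1.0
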