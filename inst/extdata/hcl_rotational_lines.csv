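J_lower,nu_exp_cm1
0,20.88
1,41.74
2,62.58
3,83.32
4,104.13
5,124.73
6,145.37
7,165.89
8,186.23
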