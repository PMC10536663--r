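participant,min_entropy,max_entropy,mean_entropy,initial_entropy,final_entropy,variation_pct
1,0.081,0.281,0.185,0.143,0.238,66.238
11,0.044,0.184,0.109,0.137,0.122,-10.972
13,0.036,0.145,0.067,0.044,0.047,5.746
14,0.006,0.233,0.144,0.145,0.184,27.016
15,0.106,0.236,0.16,0.168,0.152,-9.748
16,0.076,0.241,0.154,0.172,0.118,-31.092
17,0.116,0.431,0.198,0.179,0.289,60.805
18,0.062,0.129,0.098,0.096,0.094,-1.45
19,0.08,0.298,0.14,0.098,0.08,-19.156
21,0.083,0.29,0.135,0.104,0.141,36.39
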