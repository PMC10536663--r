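participant,min_entropy,max_entropy,mean_entropy,initial_entropy,final_entropy,variation_pct
1,0.682,0.755,0.718,0.707,0.726,2.694
2,0.672,0.842,0.766,0.782,0.672,-14.079
3,0.695,0.919,0.772,0.78,0.757,-2.921
4,0.706,0.825,0.756,0.755,0.75,-0.746
6,0.706,0.738,0.722,0.729,0.738,1.25
9,0.719,0.78,0.745,0.719,0.76,5.676
10,0.67,0.793,0.733,0.754,0.746,-1.068
14,0.665,0.755,0.713,0.691,0.725,4.841
16,0.688,0.798,0.75,0.72,0.754,4.846
17,0.659,0.718,0.683,0.684,0.683,-0.101
18,0.642,0.773,0.709,0.706,0.714,1.156
20,0.68,0.723,0.697,0.695,0.696,0.041
21,0.708,0.918,0.752,0.743,0.724,-2.576
22,0.676,0.814,0.715,0.73,0.727,-0.494
24,0.636,1.111,0.783,0.765,0.636,-16.771
25,0.638,0.748,0.711,0.703,0.711,1.138
26,0.674,0.86,0.712,0.702,0.86,22.495
27,0.637,0.781,0.713,0.723,0.757,4.658
28,0.718,0.812,0.756,0.773,0.753,-2.529
31,0.697,0.842,0.753,0.754,0.714,-5.306
32,0.682,0.923,0.742,0.788,0.714,-9.422
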