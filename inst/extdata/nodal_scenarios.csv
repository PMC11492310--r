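scenario,LN_Ib_L,LN_Ib_R,LN_II_L,LN_II_R,LN_III_L,LN_III_R,LN_IV_L,LN_IV_R,LN_Va_L,LN_Va_R,LN_Vb_L,LN_Vb_R
1,none,none,ctv3n,ctv3n,ctv3n,ctv3n,ctv4,ctv4,ctv3n,ctv3n,ctv4,ctv4
2,ctv3n,ctv3n,ctv3n,ctv3n,ctv3n,ctv3n,ctv4,ctv4,ctv3n,ctv3n,ctv4,ctv4
3,ctv3n,none,ctv3n,ctv3n,ctv3n,ctv3n,ctv4,ctv4,ctv3n,ctv3n,ctv4,ctv4
4,none,ctv3n,ctv3n,ctv3n,ctv3n,ctv3n,ctv4,ctv4,ctv3n,ctv3n,ctv4,ctv4
5,ctv3n,ctv3n,ctv3n,ctv3n,ctv3n,ctv3n,ctv3n,ctv3n,ctv3n,ctv3n,ctv3n,ctv3n
6,ctv3n,ctv3n,ctv3n,ctv3n,ctv3n,ctv3n,ctv3n,ctv4,ctv3n,ctv3n,ctv3n,ctv4
7,ctv3n,ctv3n,ctv3n,ctv3n,ctv3n,ctv3n,ctv4,ctv3n,ctv3n,ctv3n,ctv4,ctv3n
8,ctv3n,none,ctv3n,ctv3n,ctv3n,ctv3n,ctv3n,ctv4,ctv3n,ctv3n,ctv3n,ctv4
9,none,ctv3n,ctv3n,ctv3n,ctv3n,ctv3n,ctv4,ctv3n,ctv3n,ctv3n,ctv4,ctv3n
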