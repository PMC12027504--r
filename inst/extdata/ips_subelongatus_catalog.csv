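"peak_no","label","chc_class","chain","methyls","double_bonds","rt_min","ki","diagnostic_ions","alt_label"
1,"7-C25:1","alkene",25,"","7",34.04,2480,"83;97;111;350",""
2,"n-C25","n_alkane",25,"","",34.29,2500,"352",""
3,"3-meC25","monomethyl",25,"3","",35.21,2572,"337;366",""
4,"n-C26","n_alkane",26,"","",35.56,2600,"366",""
5,"4-meC26","monomethyl",26,"4","",36.27,2657,"43;71;337;380",""
6,"9-C27:1","alkene",27,"","9",36.52,2677,"83;97;111;378",""
7,"7-C27:1","alkene",27,"","7",36.6,2684,"83;97;111;378",""
8,"n-C27","n_alkane",27,"","",36.8,2700,"380",""
9,"11-meC27","monomethyl",27,"11","",37.19,2733,"168;252",""
10,"7-meC27","monomethyl",27,"7","",37.29,2741,"112;309",""
11,"5-meC27","monomethyl",27,"5","",37.39,2750,"85;337",""
12,"3-meC27","monomethyl",27,"3","",37.68,2774,"365;394",""
13,"n-C28","n_alkane",28,"","",37.99,2800,"394",""
14,"3,7-dimeC27","dimethyl",27,"3;7","",38.09,2809,"393;379;126;308",""
15,"4-meC28","monomethyl",28,"4","",38.67,2858,"43;71;365",""
16,"9-C29:1","alkene",29,"","9",38.92,2879,"406;83;97;111",""
17,"7-C29:1","alkene",29,"","7",38.99,2885,"406;71;83;97;111",""
18,"n-C29","n_alkane",29,"","",39.16,2900,"408",""
19,"13-meC29","monomethyl",29,"13","",39.5,2930,"196;224;252;407",""
20,"7-meC29","monomethyl",29,"7","",39.6,2938,"112;337;407",""
21,"5-meC29","monomethyl",29,"5","",39.71,2948,"85;365;407",""
22,"9,13-dimeC29","dimethyl",29,"9;13","",39.83,2958,"421;323;252;211;140",""
23,"5,X-dimeC29","dimethyl",29,"5;X","",40.04,2977,"85;196;211;379;421",""
24,"n-C30","n_alkane",30,"","",40.31,3000,"422",""
25,"7-C31:1","alkene",31,"","7",41.15,3073,"83;97;111;434","9-C31:1"
26,"15-meC31","monomethyl",31,"15","",41.71,3121,"196;224;252",""
27,"7-meC31","monomethyl",31,"7","",41.84,3133,"112;365;436",""
28,"11,15-dimeC31","dimethyl",31,"11;15","",42.04,3150,"168;239;252;323",""
29,"4-meC31","monomethyl",31,"4","",42.19,3163,"71;379;450",""
30,"5,17-dimeC31","dimethyl",31,"5;17","",42.3,3173,"85;126;168;225;267;407",""
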