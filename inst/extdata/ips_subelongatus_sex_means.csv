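"peak_no","label","male_mean","male_se","female_mean","female_se"
1,"7-C25:1",0.6,0.1,0.6,0.1
2,"n-C25",17.5,1.6,11.1,1.4
3,"3-meC25",1.4,0.1,1.3,0.1
4,"n-C26",3.1,0.4,2.7,0.4
5,"4-meC26",0.4,0,0.6,0.1
6,"9-C27:1",16.8,1.7,15.8,2
7,"7-C27:1",5.3,0.4,4.8,0.6
8,"n-C27",21.8,1.6,19.5,1.7
9,"11-meC27",0.7,0.1,0.9,0.1
10,"7-meC27",0.2,0,0.4,0
11,"5-meC27",2,0.1,2.4,0.2
12,"3-meC27",7,0.5,7.9,0.5
13,"n-C28",1.7,0.2,2,0.2
14,"3,7-dimeC27",1.6,0.1,1.7,0.1
15,"4-meC28",1.1,0.1,1.7,0.2
16,"9-C29:1",2,0.2,2.3,0.2
17,"7-C29:1",1.4,0.1,1.6,0.1
18,"n-C29",2.4,0.1,2.8,0.2
19,"13-meC29",1.1,0.3,1.6,0.4
20,"7-meC29",1.2,0.2,2,0.3
21,"5-meC29",1.2,0.2,1.6,0.2
22,"9,13-dimeC29",0.8,0.2,1.1,0.3
23,"5,X-dimeC29",2.5,0.7,4.2,0.9
24,"n-C30",0.5,0.1,0.5,0.1
25,"7-C31:1",0.5,0.1,0.5,0.1
26,"15-meC31",1.6,0.5,2.6,0.6
27,"7-meC31",0.4,0.1,0.7,0.2
28,"11,15-dimeC31",0.7,0.2,1.1,0.3
29,"4-meC31",0.9,0.2,1.5,0.4
30,"5,17-dimeC31",1.7,0.5,2.7,0.7
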