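"population","n","peak_no","label","mean","se"
"MJHL",10,1,"7-C25:1",0.7,0.1
"MJHL",10,2,"n-C25",12.3,1.3
"MJHL",10,3,"3-meC25",1.7,0.1
"MJHL",10,4,"n-C26",5.6,0.5
"MJHL",10,5,"4-meC26",0.7,0.1
"MJHL",10,6,"9-C27:1",13.5,0.8
"MJHL",10,7,"7-C27:1",5.3,0.5
"MJHL",10,8,"n-C27",23.5,1.8
"MJHL",10,9,"11-meC27",1.2,0.2
"MJHL",10,10,"7-meC27",0.3,0.1
"MJHL",10,11,"5-meC27",2.9,0.2
"MJHL",10,12,"3-meC27",11.2,0.3
"MJHL",10,13,"n-C28",3.3,0.3
"MJHL",10,14,"3,7-dimeC27",2.2,0.2
"MJHL",10,15,"4-meC28",1.7,0.1
"MJHL",10,16,"9-C29:1",1.5,0.2
"MJHL",10,17,"7-C29:1",1.2,0.1
"MJHL",10,18,"n-C29",3.2,0.3
"MJHL",10,19,"13-meC29",0.6,0.2
"MJHL",10,20,"7-meC29",1.4,0.2
"MJHL",10,21,"5-meC29",1.7,0.1
"MJHL",10,22,"9,13-dimeC29",,
"MJHL",10,23,"5,X-dimeC29",1.5,0.4
"MJHL",10,24,"n-C30",0.8,0.1
"MJHL",10,25,"7-C31:1",0.3,0.1
"MJHL",10,26,"15-meC31",0.7,0.1
"MJHL",10,27,"7-meC31",,
"MJHL",10,28,"11,15-dimeC31",,
"MJHL",10,29,"4-meC31",0.6,0.1
"MJHL",10,30,"5,17-dimeC31",0.5,0.1
"WDLN",12,1,"7-C25:1",0.9,0.1
"WDLN",12,2,"n-C25",17.1,1.9
"WDLN",12,3,"3-meC25",1.6,0.1
"WDLN",12,4,"n-C26",4.2,0.4
"WDLN",12,5,"4-meC26",0.5,0.1
"WDLN",12,6,"9-C27:1",18.6,1.4
"WDLN",12,7,"7-C27:1",7.4,0.7
"WDLN",12,8,"n-C27",27.6,1.2
"WDLN",12,9,"11-meC27",0.3,0.1
"WDLN",12,10,"7-meC27",0.1,0.1
"WDLN",12,11,"5-meC27",1.8,0.2
"WDLN",12,12,"3-meC27",7.3,0.4
"WDLN",12,13,"n-C28",2.2,0.2
"WDLN",12,14,"3,7-dimeC27",1.2,0.1
"WDLN",12,15,"4-meC28",1,0.2
"WDLN",12,16,"9-C29:1",2,0.2
"WDLN",12,17,"7-C29:1",1.3,0.1
"WDLN",12,18,"n-C29",3.1,0.3
"WDLN",12,19,"13-meC29",,
"WDLN",12,20,"7-meC29",0.6,0.4
"WDLN",12,21,"5-meC29",0.8,0.2
"WDLN",12,22,"9,13-dimeC29",,
"WDLN",12,23,"5,X-dimeC29",0.3,0.1
"WDLN",12,24,"n-C30",,
"WDLN",12,25,"7-C31:1",0.1,0.1
"WDLN",12,26,"15-meC31",,
"WDLN",12,27,"7-meC31",,
"WDLN",12,28,"11,15-dimeC31",,
"WDLN",12,29,"4-meC31",,
"WDLN",12,30,"5,17-dimeC31",,
"GHIM",10,1,"7-C25:1",0.1,0.1
"GHIM",10,2,"n-C25",6.5,0.9
"GHIM",10,3,"3-meC25",0.8,0.1
"GHIM",10,4,"n-C26",1.2,0.2
"GHIM",10,5,"4-meC26",0.4,0.1
"GHIM",10,6,"9-C27:1",10.1,1.4
"GHIM",10,7,"7-C27:1",2.4,0.3
"GHIM",10,8,"n-C27",14.1,1.4
"GHIM",10,9,"11-meC27",1.5,0.1
"GHIM",10,10,"7-meC27",0.5,0.1
"GHIM",10,11,"5-meC27",2.7,0.2
"GHIM",10,12,"3-meC27",8.5,0.5
"GHIM",10,13,"n-C28",1.5,0.2
"GHIM",10,14,"3,7-dimeC27",2.2,0.3
"GHIM",10,15,"4-meC28",1.8,0.1
"GHIM",10,16,"9-C29:1",2.8,0.2
"GHIM",10,17,"7-C29:1",2.1,0.2
"GHIM",10,18,"n-C29",2.4,0.2
"GHIM",10,19,"13-meC29",3.4,0.3
"GHIM",10,20,"7-meC29",2.9,0.3
"GHIM",10,21,"5-meC29",2.2,0.2
"GHIM",10,22,"9,13-dimeC29",2.5,0.3
"GHIM",10,23,"5,X-dimeC29",8.2,1
"GHIM",10,24,"n-C30",1.2,0.2
"GHIM",10,25,"7-C31:1",0.9,0.1
"GHIM",10,26,"15-meC31",4.3,0.4
"GHIM",10,27,"7-meC31",1,0.1
"GHIM",10,28,"11,15-dimeC31",2.4,0.3
"GHIM",10,29,"4-meC31",3.5,0.5
"GHIM",10,30,"5,17-dimeC31",6,0.6
"YCHL",8,1,"7-C25:1",0.1,0
"YCHL",8,2,"n-C25",5.2,0.8
"YCHL",8,3,"3-meC25",0.7,0.1
"YCHL",8,4,"n-C26",0.9,0.1
"YCHL",8,5,"4-meC26",0.8,0.5
"YCHL",8,6,"9-C27:1",4.4,0.4
"YCHL",8,7,"7-C27:1",1.8,0.2
"YCHL",8,8,"n-C27",8.1,1.1
"YCHL",8,9,"11-meC27",1.7,0.2
"YCHL",8,10,"7-meC27",0.5,0.1
"YCHL",8,11,"5-meC27",2.7,0.3
"YCHL",8,12,"3-meC27",7,0.8
"YCHL",8,13,"n-C28",2.2,0.5
"YCHL",8,14,"3,7-dimeC27",1.9,0.1
"YCHL",8,15,"4-meC28",3.2,0.3
"YCHL",8,16,"9-C29:1",2.2,0.2
"YCHL",8,17,"7-C29:1",2.3,0.1
"YCHL",8,18,"n-C29",2.4,0.2
"YCHL",8,19,"13-meC29",4.3,0.3
"YCHL",8,20,"7-meC29",4.2,0.2
"YCHL",8,21,"5-meC29",3.1,0.2
"YCHL",8,22,"9,13-dimeC29",3.4,0.4
"YCHL",8,23,"5,X-dimeC29",10.6,0.3
"YCHL",8,24,"n-C30",0.8,0.1
"YCHL",8,25,"7-C31:1",1.3,0.19
"YCHL",8,26,"15-meC31",8,1.08
"YCHL",8,27,"7-meC31",2.1,0.14
"YCHL",8,28,"11,15-dimeC31",3.4,0.36
"YCHL",8,29,"4-meC31",3.2,0.2
"YCHL",8,30,"5,17-dimeC31",7.2,0.3
"EDJL",12,1,"7-C25:1",0.7,0.1
"EDJL",12,2,"n-C25",26.8,1.3
"EDJL",12,3,"3-meC25",1.7,0.1
"EDJL",12,4,"n-C26",2.6,0.1
"EDJL",12,5,"4-meC26",0.3,0.1
"EDJL",12,6,"9-C27:1",17.6,0.7
"EDJL",12,7,"7-C27:1",6.1,0.5
"EDJL",12,8,"n-C27",29.3,1
"EDJL",12,9,"11-meC27",0.02,0
"EDJL",12,10,"7-meC27",0.1,0.1
"EDJL",12,11,"5-meC27",1.3,0.1
"EDJL",12,12,"3-meC27",4.7,0.4
"EDJL",12,13,"n-C28",0.9,0.1
"EDJL",12,14,"3,7-dimeC27",1.3,0.1
"EDJL",12,15,"4-meC28",0.2,0.1
"EDJL",12,16,"9-C29:1",1.7,0.1
"EDJL",12,17,"7-C29:1",0.8,0.1
"EDJL",12,18,"n-C29",2.7,0.2
"EDJL",12,19,"13-meC29",,
"EDJL",12,20,"7-meC29",0.1,0.1
"EDJL",12,21,"5-meC29",0.2,0.1
"EDJL",12,22,"9,13-dimeC29",,
"EDJL",12,23,"5,X-dimeC29",0.1,0.1
"EDJL",12,24,"n-C30",,
"EDJL",12,25,"7-C31:1",0.2,0.1
"EDJL",12,26,"15-meC31",0.3,0.1
"EDJL",12,27,"7-meC31",0.2,0.1
"EDJL",12,28,"11,15-dimeC31",,
"EDJL",12,29,"4-meC31",,
"EDJL",12,30,"5,17-dimeC31",,
"ARIM",6,1,"7-C25:1",0.8,0.1
"ARIM",6,2,"n-C25",13.4,0.8
"ARIM",6,3,"3-meC25",1.5,0.2
"ARIM",6,4,"n-C26",1.6,0.3
"ARIM",6,5,"4-meC26",0.5,0.1
"ARIM",6,6,"9-C27:1",39.4,2.2
"ARIM",6,7,"7-C27:1",6.7,0.6
"ARIM",6,8,"n-C27",12,0.9
"ARIM",6,9,"11-meC27",0.5,0.1
"ARIM",6,10,"7-meC27",0.3,0.1
"ARIM",6,11,"5-meC27",1.9,0.2
"ARIM",6,12,"3-meC27",5,0.6
"ARIM",6,13,"n-C28",0.5,0.1
"ARIM",6,14,"3,7-dimeC27",1.6,0.2
"ARIM",6,15,"4-meC28",1.1,0.1
"ARIM",6,16,"9-C29:1",3.5,0.3
"ARIM",6,17,"7-C29:1",1.8,0.3
"ARIM",6,18,"n-C29",1,0.1
"ARIM",6,19,"13-meC29",0.6,0.1
"ARIM",6,20,"7-meC29",1,0.1
"ARIM",6,21,"5-meC29",0.6,0.1
"ARIM",6,22,"9,13-dimeC29",0.2,0.1
"ARIM",6,23,"5,X-dimeC29",1.4,0.2
"ARIM",6,24,"n-C30",0.4,0.1
"ARIM",6,25,"7-C31:1",0.5,0.2
"ARIM",6,26,"15-meC31",0.7,0.1
"ARIM",6,27,"7-meC31",0.1,0.1
"ARIM",6,28,"11,15-dimeC31",0.2,0
"ARIM",6,29,"4-meC31",0.5,0.1
"ARIM",6,30,"5,17-dimeC31",0.7,0.1
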