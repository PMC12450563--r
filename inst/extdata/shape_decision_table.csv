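"s1","s2","s3","s4","guard_a","guard_b","shape_gt","shape_eq","shape_lt","provenance"
-1,-1,-1,-1,,,"pyramid","pyramid","pyramid","anchored"
-1,-1,-1,0,,,"plunger","plunger","plunger","anchored"
-1,-1,-1,1,5,3,"hourglass","hourglass","pyramid","anchored"
-1,-1,0,-1,,,"pyramid","pyramid","pyramid","reconstructed"
-1,-1,0,0,,,"plunger","plunger","plunger","anchored"
-1,-1,0,1,5,2,"hourglass","hourglass","pyramid","reconstructed"
-1,-1,1,-1,4,2,"upper_diamond","pyramid","pyramid","reconstructed"
-1,-1,1,0,5,2,"hourglass","hourglass","plunger","reconstructed"
-1,-1,1,1,4,2,"inverted_pyramid","hourglass","pyramid","reconstructed"
-1,0,-1,-1,,,"pyramid","pyramid","pyramid","reconstructed"
-1,0,-1,0,,,"plunger","plunger","plunger","anchored"
-1,0,-1,1,5,3,"hourglass","hourglass","pyramid","reconstructed"
-1,0,0,-1,,,"pyramid","pyramid","pyramid","anchored"
-1,0,0,0,,,"plunger","plunger","plunger","anchored"
-1,0,0,1,5,1,"inverted_pyramid","hourglass","pyramid","reconstructed"
-1,0,1,-1,4,1,"upper_diamond","pyramid","pyramid","reconstructed"
-1,0,1,0,5,1,"hourglass","hourglass","plunger","reconstructed"
-1,0,1,1,1,4,"hourglass","hourglass","inverted_pyramid","reconstructed"
-1,1,-1,-1,3,1,"middle_diamond","pyramid","pyramid","reconstructed"
-1,1,-1,0,3,1,"middle_diamond","plunger","plunger","reconstructed"
-1,1,-1,1,,,"hourglass","hourglass","hourglass","reconstructed"
-1,1,0,-1,3,1,"upper_diamond","pyramid","pyramid","reconstructed"
-1,1,0,0,5,1,"hourglass","hourglass","plunger","reconstructed"
-1,1,0,1,1,3,"hourglass","hourglass","inverted_pyramid","reconstructed"
-1,1,1,-1,4,1,"upper_diamond","pyramid","pyramid","reconstructed"
-1,1,1,0,1,3,"hourglass","hourglass","inverted_bell","reconstructed"
-1,1,1,1,1,3,"hourglass","hourglass","inverted_pyramid","reconstructed"
0,-1,-1,-1,,,"bell","bell","bell","anchored"
0,-1,-1,0,,,"plunger","plunger","plunger","reconstructed"
0,-1,-1,1,5,3,"hourglass","hourglass","bell","reconstructed"
0,-1,0,-1,,,"bell","bell","bell","reconstructed"
0,-1,0,0,,,"plunger","plunger","plunger","reconstructed"
0,-1,0,1,1,5,"hourglass","hourglass","inverted_plunger","reconstructed"
0,-1,1,-1,4,2,"upper_diamond","bell","bell","reconstructed"
0,-1,1,0,4,2,"inverted_bell","hourglass","bell","reconstructed"
0,-1,1,1,1,4,"hourglass","hourglass","inverted_plunger","reconstructed"
0,0,-1,-1,,,"bell","bell","bell","reconstructed"
0,0,-1,0,,,"plunger","plunger","plunger","reconstructed"
0,0,-1,1,1,5,"hourglass","hourglass","inverted_plunger","reconstructed"
0,0,0,-1,,,"bell","bell","bell","reconstructed"
0,0,0,0,,,"column","column","column","anchored"
0,0,0,1,,,"inverted_plunger","inverted_plunger","inverted_plunger","reconstructed"
0,0,1,-1,,,"upper_diamond","upper_diamond","upper_diamond","reconstructed"
0,0,1,0,,,"inverted_plunger","inverted_plunger","inverted_plunger","reconstructed"
0,0,1,1,,,"inverted_plunger","inverted_plunger","inverted_plunger","reconstructed"
0,1,-1,-1,,,"middle_diamond","middle_diamond","middle_diamond","reconstructed"
0,1,-1,0,,,"middle_diamond","middle_diamond","middle_diamond","reconstructed"
0,1,-1,1,3,5,"middle_diamond","inverted_plunger","inverted_plunger","reconstructed"
0,1,0,-1,2,4,"lower_diamond","middle_diamond","upper_diamond","reconstructed"
0,1,0,0,,,"inverted_plunger","inverted_plunger","inverted_plunger","reconstructed"
0,1,0,1,,,"inverted_plunger","inverted_plunger","inverted_plunger","reconstructed"
0,1,1,-1,,,"upper_diamond","upper_diamond","upper_diamond","reconstructed"
0,1,1,0,,,"inverted_plunger","inverted_plunger","inverted_plunger","reconstructed"
0,1,1,1,,,"inverted_plunger","inverted_plunger","inverted_plunger","reconstructed"
1,-1,-1,-1,,,"lower_diamond","lower_diamond","lower_diamond","reconstructed"
1,-1,-1,0,,,"lower_diamond","lower_diamond","lower_diamond","reconstructed"
1,-1,-1,1,2,5,"lower_diamond","inverted_pyramid","inverted_pyramid","reconstructed"
1,-1,0,-1,,,"lower_diamond","lower_diamond","lower_diamond","reconstructed"
1,-1,0,0,,,"lower_diamond","lower_diamond","lower_diamond","reconstructed"
1,-1,0,1,2,5,"lower_diamond","inverted_pyramid","inverted_pyramid","reconstructed"
1,-1,1,-1,2,4,"lower_diamond","middle_diamond","upper_diamond","reconstructed"
1,-1,1,0,2,4,"lower_diamond","inverted_bell","inverted_bell","reconstructed"
1,-1,1,1,2,4,"lower_diamond","inverted_pyramid","inverted_pyramid","reconstructed"
1,0,-1,-1,2,4,"lower_diamond","middle_diamond","upper_diamond","reconstructed"
1,0,-1,0,2,4,"lower_diamond","middle_diamond","upper_diamond","reconstructed"
1,0,-1,1,3,5,"lower_diamond","inverted_pyramid","inverted_pyramid","reconstructed"
1,0,0,-1,2,4,"lower_diamond","middle_diamond","upper_diamond","reconstructed"
1,0,0,0,,,"inverted_bell","inverted_bell","inverted_bell","reconstructed"
1,0,0,1,,,"inverted_pyramid","inverted_pyramid","inverted_pyramid","reconstructed"
1,0,1,-1,,,"upper_diamond","upper_diamond","upper_diamond","reconstructed"
1,0,1,0,,,"inverted_bell","inverted_bell","inverted_bell","reconstructed"
1,0,1,1,,,"inverted_pyramid","inverted_pyramid","inverted_pyramid","reconstructed"
1,1,-1,-1,,,"middle_diamond","middle_diamond","middle_diamond","reconstructed"
1,1,-1,0,,,"middle_diamond","middle_diamond","middle_diamond","reconstructed"
1,1,-1,1,3,5,"middle_diamond","inverted_pyramid","inverted_pyramid","reconstructed"
1,1,0,-1,2,4,"lower_diamond","middle_diamond","upper_diamond","reconstructed"
1,1,0,0,,,"inverted_bell","inverted_bell","inverted_bell","reconstructed"
1,1,0,1,,,"inverted_pyramid","inverted_pyramid","inverted_pyramid","reconstructed"
1,1,1,-1,,,"upper_diamond","upper_diamond","upper_diamond","reconstructed"
1,1,1,0,,,"inverted_bell","inverted_bell","inverted_bell","reconstructed"
1,1,1,1,,,"inverted_pyramid","inverted_pyramid","inverted_pyramid","anchored"
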