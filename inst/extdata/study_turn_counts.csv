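participant,experience,group,carving_long,carving_medium,carving_short,drifting_long,drifting_medium,drifting_short
1,WC,Ref,10,42,29,9,25,1
3,WC,Test,3,4,0,0,0,0
4,Instructor,Test,0,0,0,0,0,34
5,Instructor,Test,0,0,0,0,0,37
6,FIS,Test,0,0,0,0,18,10
7,Instructor,Test,0,0,0,0,1,23
8,Instructor,Test,0,0,12,0,0,22
9,Instructor,Test,0,0,5,0,2,18
11,Instructor,Test,0,0,0,0,2,15
12,Instructor,Test,1,10,7,0,0,17
14,Instructor,Test,15,16,2,8,11,2
15,FIS,Test,4,42,22,5,17,47
16,Instructor,Test,0,33,4,7,43,35
17,Instructor,Ref,2,73,12,14,24,3
19,Instructor,Ref,8,18,30,6,12,5
20,Instructor,Test,5,54,25,12,22,45
21,FIS,Test,13,21,14,6,16,20
23,WC,Ref,10,59,59,20,6,27
24,WC,Ref,11,43,0,21,9,0
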