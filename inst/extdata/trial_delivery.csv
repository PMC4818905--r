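patient,phase,mu_reference,mu_comparator,time_reference,time_comparator,gamma_reference,gamma_comparator
1,1,609,792,8:13,5:15,100.0,98.4
1,2,515,671,8:03,3:49,100.0,96.8
1,3,599,777,6:05,3:41,100.0,98.5
2,1,646,742,9:00,4:27,100.0,98.6
2,2,646,803,8:13,3:30,100.0,97.5
2,3,448,616,5:50,3:35,99.4,98.9
3,1,415,725,6:11,3:56,100.0,97.8
3,2,436,734,6:30,3:15,100.0,96.1
3,3,310,877,5:00,4:12,97.3,94.3
4,1,384,737,5:50,3:48,100.0,98.8
4,2,409,671,5:55,4:12,99.6,98.6
4,3,283,575,5:02,3:05,99.4,98.7
5,1,438,719,5:50,3:47,100.0,99.7
5,2,417,751,6:12,3:12,100.0,97.4
5,3,235,226,4:24,1:27,100.0,100.0
6,1,520,809,6:13,3:14,100.0,99.8
6,2,466,748,5:55,3:23,100.0,98.4
6,3,263,424,4:22,2:35,100.0,100.0
7,1,538,695,6:10,4:20,100.0,99.9
7,2,591,738,6:30,3:49,100.0,100.0
7,3,263,664,5:00,3:05,99.5,99.4
8,1,689,672,9:00,3:36,99.7,99.0
8,2,437,595,6:32,4:06,100.0,100.0
8,3,368,740,4:15,3:54,99.8,98.2
9,1,450,708,5:26,4:51,100.0,99.2
9,2,464,674,5:41,3:34,99.9,99.7
9,3,315,322,4:46,1:56,98.4,100.0
10,1,545,746,6:47,5:03,100.0,100.0
10,2,562,759,7:07,4:37,99.8,98.6
10,3,336,270,5:25,1:52,99.4,99.6
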