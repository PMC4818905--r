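patient,phase,structure,reference_qf_pct,comparator_qf_pct
1,1,GTV_T,5.1,3.9
1,1,GTV_N1,1.8,1.5
1,1,GTV_N2,2.8,2.0
1,2,GTV_T,4.3,2.8
1,2,GTV_N1,4.6,1.4
2,1,GTV_T,5.0,3.6
2,1,GTV_N1,3.1,2.9
2,2,GTV_T,4.0,3.2
2,2,GTV_N1,5.3,3.8
3,1,GTV_T,4.3,2.8
3,2,GTV_T,3.6,2.2
4,1,GTV_T,4.0,4.5
4,2,GTV_T,2.6,3.4
5,1,GTV_T,5.1,3.5
5,2,GTV_T,4.5,3.1
6,1,GTV_T,4.6,2.9
6,2,GTV_T,3.2,2.8
7,1,GTV_T,3.8,4.1
7,2,GTV_T,3.4,2.9
8,1,GTV_T,4.0,2.3
8,1,GTV_N1,2.2,2.5
8,1,GTV_N2,2.6,2.7
8,2,GTV_T,4.9,2.8
9,1,GTV_T,3.5,1.9
9,2,GTV_T,2.8,1.4
10,1,GTV_T,5.1,4.1
10,1,GTV_N1,3.9,3.4
10,2,GTV_T,5.1,4.2
10,2,GTV_N1,5.1,2.4
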