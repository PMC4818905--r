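patient,reference_J,comparator_J,delta_pct
1,243.1,238.4,-1.9
2,274.4,274.3,0.0
3,115.3,109.1,-5.4
4,125.1,123.6,-1.2
5,135.3,129.1,-4.6
6,120.5,124.9,3.7
7,130.2,128.9,-1.0
8,150.1,128.6,-14.4
9,104.4,101.6,-2.7
10,160.1,164.6,2.8
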