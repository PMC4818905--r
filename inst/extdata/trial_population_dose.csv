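structure,metric,reference,comparator
GTV_T,D2,80.4,81.0
GTV_T,D98,67.3,68.4
GTV_N,D2,73.3,74.8
GTV_N,D98,64.8,66.3
PTV_HR,D2,76.9,77.9
PTV_HR,D98,57.5,56.9
PTV_EN,D2,66.0,67.0
PTV_EN,D98,32.2,32.7
CTV_HR,D2,78.1,79.1
CTV_HR,D98,60.9,60.3
CTV_EN,D2,66.5,67.8
CTV_EN,D98,38.9,38.6
spinal_cord_PRV,D5,32.4,28.4
spinal_cord_PRV,D50,21.4,13.6
brainstem_PRV,D5,20.5,14.2
brainstem_PRV,D50,2.3,2.1
parotid_ipsi,V27Gy,43.8,36.6
parotid_ipsi,Dmean,25.8,22.2
parotid_contra,V27Gy,40.0,33.0
parotid_contra,Dmean,24.4,21.3
PC,D2,67.3,67.6
PC,D50,57.0,53.4
PC,D98,36.3,25.1
SS,D2,68.0,68.0
SS,D50,53.5,47.4
SS,D98,34.3,23.3
mandible,D2,53.6,53.6
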