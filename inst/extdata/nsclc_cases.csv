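case_id,histology,volume_ct1_mm3,volume_ct2_mm3,reduction_pct,interval_cts_d,interval_ct1_onset_d,ckr_b,interval_ct2_surgery_d,resect_a_cm,resect_b_cm,resect_c_cm
1,SCC,100264,46776,53.35,47,5,0.2,20,6,4.5,3
2,SCC,568264,168048,70.43,46,4,0.2,21,6,5.5,4
3,SCC,101216,26336,73.98,45,4,0.2,18,2.5,1.6,1.6
4,SCC,41376,18352,55.65,67,27,0.2,36,3,2,1.5
5,SCC,20760,5824,71.95,90,47,0.2,5,2.5,1.8,1.5
6,SCC,41056,23416,42.97,63,14,0.2,39,4,3.7,3
7,SCC,39776,15840,60.18,42,-1,0.2,7,3.5,3.3,2.5
8,SCC,133864,29816,77.73,47,5,0.2,3,3.5,3.5,3.3
9,SCC,123016,131160,-6.62,83,27,0.1,28,8,7.5,5.5
10,ADC,45160,8544,81.08,69,27,0.2,20,2.1,1.9,1.3
11,ADC,63136,20632,67.32,46,0,0.2,6,4,3.5,2
12,ADC,99872,51752,48.18,60,18,0.2,NA,NA,NA,NA
13,ADC,111744,29264,73.81,104,21,0.2,22,4.7,4,3.1
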