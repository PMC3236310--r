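"culture_id","uptake","b1","b2","b3","target"
"1",46.7528,23.9835,7.466,8.123,-0.4906
"2",23.2004,7.9453,7.709,4.5722,-1.3547
"3",38.8713,13.9833,17.0698,15.3881,1.3641
"4",30.9712,15.7437,9.0331,5.9709,-0.7094
"5",30.4301,13.6519,2.687,10.8279,-1.1081
"6",27.0431,7.9005,2.8945,11.6492,-0.6586
"7",29.9221,20.9851,15.6516,12.8616,4.0223
"8",26.6534,10.4892,9.4186,7.4696,-0.9976
"9",41.8009,23.2489,3.9613,14.2174,-0.3851
"10",23.7903,8.8496,8.908,5.0523,-1.5723
"11",48.4381,20.9871,21.0965,7.8847,1.3194
"12",77.968,35.2276,29.1867,5.4858,2.9257
"13",14.1803,5.3641,9.8596,3.8751,-2.3053
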