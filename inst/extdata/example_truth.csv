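"culture_id","uptake","a1","b1","a2","b2","a3","b3","resp","target_true"
"1",37.339,19.8472,19.8472,8.6988,8.6988,8.793,8.793,19.8472,-0.4946
"2",21.0365,7.5401,7.5401,9.3551,9.3551,4.1413,4.1413,7.5401,-1.419
"3",38.3209,11.9909,11.9909,13.7434,13.7434,12.5866,12.5866,11.9909,1.4818
"4",29.6588,13.7222,13.7222,8.6751,8.6751,7.2615,7.2615,13.7222,-0.8514
"5",27.447,12.2401,12.2401,2.6495,2.6495,12.5574,12.5574,12.2401,-0.9553
"6",26.6599,9.4832,9.4832,2.9516,2.9516,14.225,14.225,9.4832,-0.5062
"7",57.4205,21.2923,21.2923,19.349,19.349,16.7791,16.7791,21.2923,3.6726
"8",25.4915,9.5377,9.5377,8.5786,8.5786,7.3752,7.3752,9.5377,-0.8465
"9",44.4104,27.4344,27.4344,4.1039,4.1039,12.8721,12.8721,27.4344,-0.5645
"10",23.1056,9.6913,9.6913,9.1763,9.1763,4.238,4.238,9.6913,-1.436
"11",44.313,19.2021,19.2021,18.3554,18.3554,6.7555,6.7555,19.2021,1.1531
"12",63.7015,31.3717,31.3717,25.795,25.795,6.5347,6.5347,31.3717,2.7322
"13",16.0477,4.9936,4.9936,8.0635,8.0635,2.9906,2.9906,4.9936,-1.9662
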