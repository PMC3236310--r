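@external S_ext P1_ext P2_ext P3_ext RQ_ext
uptake	S_ext -> Hub	true
a1	Hub + NAD -> M1 + NADH	false
b1	M1 -> P1_ext	true
a2	Hub -> M2	false
b2	M2 -> P2_ext	true
a3	Hub -> M3	false
b3	M3 -> P3_ext	true
resp	NADH -> NAD + RQ_ext	false
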