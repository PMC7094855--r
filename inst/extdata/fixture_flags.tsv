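gene	control_r1	control_r2	control_r3	control_r4	t6_r1	t6_r2	t6_r3	t6_r4	t12_r1	t12_r2	t12_r3	t12_r4	t24_r1	t24_r2	t24_r3	t24_r4
filler1	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt
filler2	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt
filler3	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt
filler4	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt
filler5	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt
filler6	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt
g_ndt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	NDt
g_cm	Dt	Dt	Dt	Dt	Cm	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt
g_gm	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt
gA	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt
gB	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt
gC	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt
gD	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt
gE	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt
gF	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt
g_neg	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt	Dt
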