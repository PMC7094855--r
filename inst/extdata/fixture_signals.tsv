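gene	control_r1	control_r2	control_r3	control_r4	t6_r1	t6_r2	t6_r3	t6_r4	t12_r1	t12_r2	t12_r3	t12_r4	t24_r1	t24_r2	t24_r3	t24_r4
filler1	256	256	256	256	256	256	256	256	256	256	256	256	256	256	256	256
filler2	256	256	256	256	256	256	256	256	256	256	256	256	256	256	256	256
filler3	256	256	256	256	256	256	256	256	256	256	256	256	256	256	256	256
filler4	256	256	256	256	256	256	256	256	256	256	256	256	256	256	256	256
filler5	256	256	256	256	256	256	256	256	256	256	256	256	256	256	256	256
filler6	256	256	256	256	256	256	256	256	256	256	256	256	256	256	256	256
g_ndt	256	256	256	256	256	256	256	256	256	256	256	256	256	256	256	256
g_cm	64	64	64	64	64	64	64	64	64	64	64	64	64	64	64	64
g_gm	2	8	2	8	2	8	2	8	2	8	2	8	2	8	2	8
gA	8	8	8	8	16	16	16	16	32	32	32	32	64	64	64	64
gB	8	8	8	8	16	16	16	16	64	64	64	64	32	32	32	32
gC	8	8	8	8	32	32	32	32	64	64	64	64	16	16	16	16
gD	8	8	8	8	64	64	64	64	32	32	32	32	16	16	16	16
gE	8	8	8	8	64	64	64	64	16	16	16	16	32	32	32	32
gF	8	8	8	8	32	32	32	32	16	16	16	16	64	64	64	64
g_neg	16	-12.4	64	64	16	16	16	16	16	16	16	16	16	16	16	16
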