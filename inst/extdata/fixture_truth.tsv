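gene	pattern	true_FC_t6	true_FC_t12	true_FC_t24	area
filler1	NA	1	1	1	NA
filler2	NA	1	1	1	NA
filler3	NA	1	1	1	NA
filler4	NA	1	1	1	NA
filler5	NA	1	1	1	NA
filler6	NA	1	1	1	NA
g_ndt	NA	1	1	1	NA
g_cm	NA	1	1	1	NA
g_gm	NA	1	1	1	NA
gA	NA	2	4	8	A
gB	NA	2	8	4	B
gC	NA	4	8	2	C
gD	NA	8	4	2	D
gE	NA	8	2	4	E
gF	NA	4	2	8	F
g_neg	NA	1	1	1	NA
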