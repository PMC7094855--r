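AREA_SET	fixture	gA	gB	gC	gD	gE	gF
FILLER_SET	fixture	filler1	filler2	filler3	filler4	filler5	filler6
MIXED_SET	fixture	gA	gB	filler1	g_gm
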