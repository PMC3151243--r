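species	gene	position_label	type	class	direction	from	to
O.latipes	MC5R	41a	SINE_FR1D	NonLTR/SINE	d	1157	1243
T.nigroviridis	MC5R	77c	(TG)n	Simple_repeat	d	301	360
G.aculeatus	MC5R	77c	UnaL2	NonLTR/L2	d	2858	2929
O.latipes	MC5R	77c	Crack-1_HM	NonLTR/Crack	d	31	108
O.latipes	MC5R	77c	DNA-8-23_DR	DNA	c	457	552
O.latipes	MC5R	77c	MRE1_OL	Interspersed_repeat	d	942	997
O.latipes	MC5R	77c	FUROUSHA2	DNA/hAT	d	1416	1530
O.latipes	MC5R	77c	DNA-8-14_DR	DNA	c	1675	1778
O.latipes	MC5R	77c	FUROUSHA2	DNA/hAT	d	2056	2121
O.latipes	MC5R	77c	FUROUSHA2	DNA/hAT	d	2187	2299
O.latipes	MC5R	77c	ERV46_MD_I	ERV/ERV1	d	2526	2578
O.latipes	MC5R	77c	Polinton-1_DR	DNA/Polinton	d	2871	2945
O.latipes	MC5R	77c	CR1-57_HM	NonLTR/CR1	c	3331	3393
O.latipes	MC5R	77c	piggyBAC-N1_OL	DNA/piggyBac	d	4080	4285
G.aculeatus	MC5R	140c	DNA-8-14_DR	DNA	c	176	236
O.latipes	MC5R	140c	SINE_FR2	NonLTR/SINE	d	434	795
O.latipes	MC5R	140c	hAT-2_NV	DNA/hAT	d	1836	1883
G.aculeatus	MC2R	140c	UnaL2	NonLTR/L2	c	554	599
G.aculeatus	MC2R	140c	Chapaev-12_HM	DNA/Chapaev	c	634	683
G.aculeatus	MC2R	140c	hAT-14_HM	DNA/hAT	c	914	1005
O.latipes	MC2R	140c	RTE-1_TD	NonLTR/RTE	d	220	297
O.latipes	MC2R	140c	DNA-TA-5_DR	DNA	c	668	789
O.latipes	MC2R	140c	RTE-2_AFC	NonLTR/RTE	d	834	1201
O.latipes	MC2R	140c	RTE-2_AFC	NonLTR/RTE	d	1213	1698
G.aculeatus	MC2R	236a	(CGG)n	Simple_repeat	d	4	33
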