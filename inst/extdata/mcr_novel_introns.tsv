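species	gene	position_label	intron_size	flank_context	gc_percent	canonical_splice	ultrasmall	deviations
T.rubripes	MC5R	41a	100	AGAG^GTCT	37	TRUE	FALSE	M
T.nigroviridis	MC5R	41a	87	AGAG^GTAA	55.2	TRUE	FALSE	M
G.aculeatus	MC5R	41a	714	CGAG^GTAT	34.5	TRUE	FALSE	M
O.latipes	MC5R	41a	1527	GGAG^GTCT	47.5	TRUE	FALSE	M
T.rubripes	MC5R	77c	669	GCAG^GTGA	41.3	TRUE	FALSE	.
T.nigroviridis	MC5R	77c	973	GCAG^GTGA	41.1	TRUE	FALSE	.
G.aculeatus	MC5R	77c	1294	GCAG^GTAA	41.4	TRUE	FALSE	.
O.latipes	MC5R	77c	4500	GCAG^GTGA	38.5	TRUE	FALSE	.
T.rubripes	MC5R	140c	1139	ACAG^GTAA	40	TRUE	FALSE	.
T.nigroviridis	MC5R	140c	111	ACAG^GTGA	55.9	TRUE	FALSE	.
G.aculeatus	MC5R	140c	302	ACAG^GTAA	38.7	TRUE	FALSE	.
O.latipes	MC5R	140c	1963	ACAG^GTAA	40.2	TRUE	FALSE	.
T.rubripes	MC2R	140c	120	ACAG^GTTT	40	TRUE	FALSE	.
T.nigroviridis	MC2R	140c	116	ACAG^GTAT	44	TRUE	FALSE	.
G.aculeatus	MC2R	140c	1409	ACCG^GTAC	37.6	TRUE	FALSE	A
O.latipes	MC2R	140c	1857	ATCG^GTAC	43.5	TRUE	FALSE	M,A
T.rubripes	MC2R	230c	18	GGCG^GTGG	66.7	TRUE	TRUE	M,A
G.aculeatus	MC2R	236a	33	TGGT^GGCC	93.9	TRUE	TRUE	M,A,G
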