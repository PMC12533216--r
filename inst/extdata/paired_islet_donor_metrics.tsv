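donor_id	modality	intronic_pct	features_per_barcode_median	mito_pct_median
donor1	cell	19.0	4508	3.7
donor2	cell	21.9	4132	3.5
donor3	cell	19.9	5946	3.5
donor4	cell	14.3	4219	2.8
donor1	nucleus	55.6	1740	0
donor2	nucleus	55.3	1991	0
donor3	nucleus	53.4	2506	0.007
donor4	nucleus	50.7	2657	0.014
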