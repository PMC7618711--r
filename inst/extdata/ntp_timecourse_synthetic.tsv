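species	condition	time_s	replicate	pmol_per_1e8_cells
ATP	wild_type	0	rep1	9120
ATP	wild_type	0	rep2	8870
ATP	wild_type	0	rep3	9030
ATP	wild_type	30	rep1	1420
ATP	wild_type	30	rep2	1350
ATP	wild_type	30	rep3	1490
ADP	wild_type	0	rep1	790
ADP	wild_type	0	rep2	830
ADP	wild_type	0	rep3	805
ADP	wild_type	30	rep1	2010
ADP	wild_type	30	rep2	2090
ADP	wild_type	30	rep3	1950
GTP	wild_type	0	rep1	2110
GTP	wild_type	0	rep2	2030
GTP	wild_type	0	rep3	2080
GTP	wild_type	30	rep1	420
GTP	wild_type	30	rep2	390
GTP	wild_type	30	rep3	405
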