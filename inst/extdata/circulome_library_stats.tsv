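library	timepoint	replicate	exo	mapped_reads	tbe_junction_reads	tbe_junction_rpm	circle_junction_reads	unique_circle_isoforms	circle_junction_rpm	nine_bp_dup_reads	nine_bp_dup_rpm
asexual_1	asexual	1	TRUE	1271072	0	0.0	33	27	26.0	3	2.4
asexual_2	asexual	2	TRUE	1091793	0	0.0	23	16	21.1	1	0.9
early_1	early	1	TRUE	993575	197	198.3	74	71	74.5	5	5.0
early_2	early	2	TRUE	1498785	125	83.4	61	48	40.7	5	3.3
mid_1	mid	1	TRUE	1185659	649	547.4	2176	2039	1835.3	176	148.4
mid_2	mid	2	TRUE	1095501	594	542.2	1464	1362	1336.4	72	65.7
late_1	late	1	TRUE	1085662	93	85.7	771	715	710.2	29	26.7
mid_noexo_1	mid	1	FALSE	1543270	42	27.2	199	182	128.9	73	47.3
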