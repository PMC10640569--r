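quartile	n	age_mean	age_sd	male	female	left	no_preference	right
1	21	5.46	0.69	6	15	1	3	17
2	20	8.41	1.77	11	9	1	3	16
3	20	13.1	1.07	11	9	1	1	18
4	21	17.0	0.80	9	12	0	0	21
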