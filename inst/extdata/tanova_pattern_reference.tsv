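mut_pattern	wt_pattern	count	n_down	n_up
up	up	45	13	31
up	NC	12	3	8
up	down	16	6	9
NC	up	10	7	2
NC	NC	8	5	3
NC	down	7	4	3
down	up	17	10	2
down	NC	9	8	1
down	down	22	21	1
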