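merged_id	label	age_lo	age_hi	n_male	n_female
1	6-15	6	15	10	9
2	16-21	16	25	7	18
3	26-35	26	35	9	11
4	36-40	36	45	7	9
5	46-50	46	57	6	13
6	58-70	58	70	5	10
7	71-79	71	79	7	12
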