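sex	class	node
male	principal	22
male	principal	28
male	principal	29
male	principal	30
male	principal	31
male	principal	48
male	principal	69
male	principal	75
male	principal	76
male	principal	77
male	principal	78
male	secondary	1
female	principal	22
female	principal	30
female	principal	31
female	principal	48
female	principal	69
female	principal	75
female	principal	76
female	principal	78
female	secondary	1
female	secondary	28
female	secondary	29
female	secondary	77
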