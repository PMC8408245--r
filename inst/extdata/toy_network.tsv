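reaction_id	substrate_side	product_side	lb	ub	reversible	rate_constant
v1	D	2 B	                 0	                10	0	                 2
v2	F	2 B	                 0	                10	0	                 1
v3	2 B	A + E	                 0	                10	0	                 1
v4	2 B	F	                 0	                10	0	                 1
v5	A + E	D	                 0	                10	0	                 1
v6	D	B	                 0	                10	0	                 1
v7	B	2 A	                 0	                10	0	                 2
v8	2 A	B + C	                 0	                10	0	                 2
v9	B + C	C	                 0	                10	0	                 1
v10	B + C	D	                 0	                10	0	                 2
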