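reaction_id	substrate_side	product_side	lb	ub	reversible
upt		A	                 0	                10	0
c1	A	B	                 0	                10	0
r4	A	Q	                 0	                10	0
r5	Q	B	                 0	                10	0
r6	2 B	A	                 0	                10	0
bio	B		                 0	                10	0
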