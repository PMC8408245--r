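reaction_id	k
v1	                 2
v2	                 1
v3	                 1
v4	                 1
v5	                 1
v6	                 1
v7	                 2
v8	                 2
v9	                 1
v10	                 2
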