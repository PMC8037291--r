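sequence	position_label	distance_cm	height_cm	curve_id	index_percent	instrument
A2	LINE	0	100	RL_B	69.5	ELT-400-chain
A2	LINE	0	100	LOW_AL_B	3.36	ELT-400-chain
A2	LINE	0	100	HIGH_AL_B	3.56	ELT-400-chain
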