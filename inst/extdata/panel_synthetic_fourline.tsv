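line_id	A_1	A_2	B_1	B_2	DRB1_1	DRB1_2
H9	A*02	A*03	B*35	B*44	DRB1*15	DRB1*07
CHA15	A*24	A*33	B*44	B*58	DRB1*04	DRB1*13
CHA6	A*02	A*24	B*51	B*54	DRB1*09	DRB1*04
SNU31	A*11	A*24	B*51	B*58	DRB1*15	DRB1*04
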