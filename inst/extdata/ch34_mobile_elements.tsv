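element	feature_type	CHR1	CHR2	pMOL28	pMOL30
IS1071	IS_element	3	0	0	0
IS1086	IS_element	1	1	1	0
IS1087	IS_element	2	0	0	0
IS1088	IS_element	3	6	0	0
IS1090	IS_element	4	0	0	0
ISRme1	IS_element	2	2	0	0
ISRme3	IS_element	3	5	0	2
ISRme4	IS_element	2	0	0	0
ISRme5	IS_element	3	1	0	0
ISRme6	IS_element	1	0	0	0
ISRme7	IS_element	2	0	0	0
ISRme8	IS_element	1	1	0	0
ISRme9	IS_element	0	0	1	0
ISRme10	IS_element	0	0	0	1
ISRme11	IS_element	0	2	0	0
ISRme12	IS_element	1	0	0	0
ISRme15	IS_element	0	1	0	1
ISRme17	IS_element	1	0	0	0
ISRme18	IS_element	0	0	1	0
ISRme19	IS_element	0	0	0	1
ISRme20	IS_element	1	0	0	0
Tn4378	transposon	0	0	1	0
Tn4380	transposon	0	0	0	1
Tn6048	transposon	1	2	0	0
Tn6049	transposon	7	3	1	1
Tn6050	transposon	0	2	0	0
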