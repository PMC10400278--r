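index	DQ	XGLL	LJ	JC	ALS
theta_pi	2.75E-05	2.82E-05	2.74E-05	2.79E-05	2.94E-05
tajima_d	1.076	1.075	1.061	1.092	1.28
ho	0.223	0.213	0.229	0.223	0.239
he	0.338	0.335	0.34	0.343	0.354
nei	0.345	0.341	0.347	0.349	0.36
pic	0.273	0.271	0.274	0.276	0.284
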