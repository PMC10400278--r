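population	region	n	longitude_text	latitude_text	altitude	temperature	precipitation
Deqin	DQ	29	99°03′15″ E	28°35′14″ N	3459	4.7	633.7
Xianggelila	XGLL	33	99°83′16″ E	27°90′13″ N	3321	5.5	984.2
Lijiang	LJ	33	100°23′30″ E	26°87′53″ N	2478	12.6	975.0
Jianchuan	JC	33	99°75′03″ E	26°44′35″ N	2219	13.9	987.3
Ailaoshan	ALS	33	100°42′49″ E	24°90′30″ N	2183	19.7	597.0
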