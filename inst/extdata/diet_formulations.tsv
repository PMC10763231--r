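ingredient	CD	OD	HD
Soybean protein concentrate	0	210.32	420.64
Vital gluten	0	44	88
Casein	304	152	0
Gelatin	76	38	0
Vital gluten	310	265	220
Soybean oil	84.2	82.7	81.1
Lysine	0	3.69	7.37
Methionine	7.24	9.245	11.25
VC phosphate	1	1	1
Vitamin premix	2	2	2
Mineral premix	2	2	2
Monocalcium phosphate	20	20	20
Choline chloride	2	2	2
Microcrystalline cellulose	80	80	80
Zeolite powder	111.56	88.045	64.64
Total	1000	1000	1000
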