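Sample	MCA 1016/1534	AS-PCR 1016	Sanger 1016	NGS 989/1016/1534	COI Accession-%ID
Osceola 1	IICC	no call	no call	not tested	not tested
Osceola 1	GIFC	no call	no call	no call	MN299016.1-100%
Osceola 1	GIFC	weakV G	GI	SSGIFC	MK300224.1-99.72%
Osceola 1	GIFC	weakG	no call	PPGICC	MN299016.1-99.57%
Osceola 1	VICC	weakV	no call	no call	MN299016.1-100%
Osceola 2	GIFC	weakV G	GI	SPGIFC	MK300218.1-98.87%
Osceola 2	GIFC	G	GI	SSGIFC	PP902511.1-99.57%
Osceola 2	VICC	V	no call	SSVICC	MN299016.1-100%
Control-SSVVFF	VVFF	V	VV	SSVVFF	MN299016.1-99.57%
Control-SSIICC	IICC	weakV	II	SSIICC	MN299016.1-100%
Control-PPGGFF	GGFF	G	GG	PPGGFF	MK300224.1-99.72%
Control-SSVIFC	VIFC	V	VI	SSVIFC	MK300224.1-98.03%
Control-SSVIFC	VIFC	V	VI	not tested	not tested
Control-SPGIFC	IIFC	no call	II	SSIICC	MK300224.1-99.72%
Control-NFW	no call	no call	no call	no call	no call
Osceola 3	GIFC	no call	no call	no call	no call
Osceola 3	GIFC	no call	no call	SSGGFC	PP902511.1-99.72%
Osceola 3	VGFC	V G	G	SPVGFC	MN299016.1-100%
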