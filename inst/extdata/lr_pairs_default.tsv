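ligand	receptor	class
LGALS9	HAVCR2	inhibitory
PVR	TIGIT	inhibitory
PVR	CD96	inhibitory
CD274	PDCD1	inhibitory
PDCD1LG2	PDCD1	inhibitory
CD80	CTLA4	inhibitory
CD86	CTLA4	inhibitory
HLA-E	KLRC1	inhibitory
LAG3	HLA-DRA	inhibitory
NECTIN2	TIGIT	inhibitory
CD80	CD28	stimulatory
CD86	CD28	stimulatory
ICOSLG	ICOS	stimulatory
TNFSF4	TNFRSF4	stimulatory
TNFSF9	TNFRSF9	stimulatory
TNFSF14	TNFRSF14	stimulatory
CD70	CD27	stimulatory
CD40LG	CD40	stimulatory
IL15	IL15RA	stimulatory
IL2	IL2RB	stimulatory
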