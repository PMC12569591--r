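gene	human_seq	mouse_seq	human_pos	human_res	mouse_pos
SMAD4	HUMAN_SMAD4_SYNTHETIC	MOUSE_Smad4_SYNTHETIC	361	R	360
PIK3CA	HUMAN_PIK3CA_SYNTHETIC	MOUSE_Pik3ca_SYNTHETIC	545	E	545
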