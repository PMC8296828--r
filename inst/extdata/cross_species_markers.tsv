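mouse_symbol	human_symbol	fc_mouse	fc_human
Ifit1	IFIT1	1.32	1.72
Ifitm3	IFITM3	1.25	1.28
Rhd	RHD	1.94	1.45
Rsad2	RSAD2	1.54	2.56
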