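species	block_start	block_end	charge_per_bead
NfL	1	43	0
NfL	44	143	-0.25
NfM	1	80	0
NfM	81	510	-0.1
NfH	1	166	0
NfH	167	606	-0.1
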