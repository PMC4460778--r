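sample_id	batch	class
s01	A	CTRL
s02	A	CTRL
s03	A	CTRL
s04	A	CTRL
s05	A	CTRL
s06	A	CTRL
s07	A	CTRL
s08	A	CTRL
s09	A	CTRL
s10	A	CTRL
s11	A	CTRL
s12	A	CTRL
s13	B	CTRL
s14	B	CTRL
s15	B	CTRL
s16	B	CTRL
s17	B	CTRL
s18	B	CTRL
s19	B	CTRL
s20	B	CTRL
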