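item_id	syllables	targets	realword_item_id
nw01	1	M AA1 P	rw01
nw02	1	T IY1 F	rw02
nw03	1	N UW1 S	rw03
nw04	1	P EH1 D	rw04
nw05	2	B AE1 K	rw05
nw06	2	D IH1 M	rw06
nw07	2	K AH1 N	rw07
nw08	2	F OW1 T	rw08
nw09	3	M EY1 D	rw09
nw10	3	S AA1 B	rw10
nw11	3	P UW1 K	rw11
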