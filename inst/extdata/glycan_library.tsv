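name	hex	hexnac	neuac	dhex	class	sda
Hex5HexNAc2	5	2	0	0	N	FALSE
NeuAc1Hex5HexNAc4	5	4	1	0	N	FALSE
NeuAc2Hex5HexNAc4	5	4	2	0	N	FALSE
NeuAc2Hex5HexNAc4dHex	5	4	2	1	N	FALSE
NeuAc2Hex5HexNAc5	5	5	2	0	N	TRUE
NeuAc2Hex5HexNAc5dHex_bisecting	5	5	2	1	N	FALSE
NeuAc2Hex5HexNAc6	5	6	2	0	N	TRUE
NeuAc2Hex5HexNAc6dHex	5	6	2	1	N	TRUE
Hex1HexNAc1	1	1	0	0	O	FALSE
NeuAc1Hex1HexNAc1	1	1	1	0	O	FALSE
NeuAc2Hex1HexNAc1	1	1	2	0	O	FALSE
NeuAc1Hex1HexNAc2	1	2	1	0	O	TRUE
NeuAc2Hex1HexNAc2	1	2	2	0	O	TRUE
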