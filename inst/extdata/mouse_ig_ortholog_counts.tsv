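Genome	IGs	MEGs	Others	Total
Zebrafish	91	90	39	220
Chick	78	55	0	133
Opossum	167	87	4	258
Chimp	250	59	26	335
Human	262	97	38	397
Rat	442	57	2	501
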