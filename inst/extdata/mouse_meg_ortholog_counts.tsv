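Genome	IGs	MEGs	Others	Total
Zebrafish	108	7602	1584	9294
Chick	122	7137	7	7266
Opossum	159	10304	966	11429
Chimp	523	8040	184	8747
Human	603	9520	374	10497
Rat	1171	10457	59	11687
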