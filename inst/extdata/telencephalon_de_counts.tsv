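dataset	class	n
IG	UP	37
IG	DN	9
IG	NC	387
IG	NE	653
MEG	UP	1247
MEG	DN	789
MEG	NC	13198
MEG	NE	5090
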