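ec	compound	role
3.5.1.24	taurine	production
4.1.1.18	cadaverine	production
4.1.1.17	putrescine	production
1.13.11.11	tryptophan	degradation
2.5.1.16	spermidine	production
1.1.1.1	methanol	degradation
1.3.5.1	succinate	production
2.6.1.42	alpha-ketoisovaleric acid	production
2.3.1.7	L-carnitine	production
1.4.3.22	3-aminopropanal	production
2.5.1.6	S-adenosylhomocysteine	production
6.3.5.4	L-asparagine	production
2.2.1.7	deoxyxylulose-5-phosphate	production
2.6.1.1	aspartate	production
6.3.4.5	arginine	production
2.1.2.1	glycine	production
2.6.1.42	leucine	production
2.6.1.57	phenylalanine	production
1.4.3.16	quinolinic acid	production
1.1.1.6	glycerol	degradation
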