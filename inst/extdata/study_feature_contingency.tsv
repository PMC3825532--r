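feature	Up_OL	Up_NOL	Down_OL	Down_NOL	log2_or	ci_low	ci_high	p
CGI	148	1304	17	1104	2.881	2.142	3.708	9.7E-22
Gene body	831	621	510	611	0.681	0.450	0.912	3.7E-09
Non-genic	692	760	651	470	-0.605	-0.836	-0.374	1.8E-07
Intron	783	669	489	632	0.597	0.366	0.828	2.3E-07
Exon	438	1014	255	866	0.553	0.289	0.818	2.5E-05
Promoter	108	1344	69	1052	0.293	-0.173	0.766	2.1E-01
TSS	53	1399	31	1090	0.413	-0.264	1.113	2.2E-01
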