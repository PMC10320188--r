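# gene expression ranking (signed metric, GSEA .rnk convention)
G6PD	5.2
MAP2K1	4.8
FILLER01	2.0
FILLER02	1.7
FILLER03	1.5
FILLER04	1.2
FILLER05	1.0
FILLER06	0.8
FILLER07	0.5
FILLER08	0.2
FILLER09	0.0
FILLER10	-0.2
FILLER11	-0.5
FILLER12	-0.8
FILLER13	-1.0
FILLER14	-1.2
FILLER15	-1.5
FILLER16	-1.7
FILLER17	-2.0
CDKN2A	-6.0
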