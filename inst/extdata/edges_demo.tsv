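source	target	layer	evidence
SP1	miR-200c-3p	gene-miRNA	demo
SP1	miR-125b-5p	gene-miRNA	demo
EP300	miR-150-5p	gene-miRNA	demo
SP1	CYP1B1-AS1	gene-lncRNA	demo
EP300	ZFAS1	gene-lncRNA	demo
SP1	ZFAS1	gene-lncRNA	demo
miR-200c-3p	CYP1B1-AS1	miRNA-lncRNA	demo
miR-150-5p	ZFAS1	miRNA-lncRNA	demo
miR-125b-5p	CYP1B1-AS1	miRNA-lncRNA	demo
miR-200c-3p	ZFAS1	miRNA-lncRNA	demo
EP300	miR-125b-5p	gene-miRNA	demo
ESRRA	miR-125b-5p	gene-miRNA	demo
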