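plex_id	protease	channel	day	replicate
plex_tryp	trypsin_lysc	126	0	1
plex_tryp	trypsin_lysc	127N	0	2
plex_tryp	trypsin_lysc	127C	0	3
plex_tryp	trypsin_lysc	128N	0	4
plex_tryp	trypsin_lysc	128C	2	1
plex_tryp	trypsin_lysc	129N	2	2
plex_tryp	trypsin_lysc	129C	2	3
plex_tryp	trypsin_lysc	130N	2	4
plex_tryp	trypsin_lysc	130C	6	1
plex_tryp	trypsin_lysc	131N	6	2
plex_tryp	trypsin_lysc	131C	6	3
plex_tryp	trypsin_lysc	132N	6	4
plex_chymo	chymotrypsin	126	0	1
plex_chymo	chymotrypsin	127N	0	2
plex_chymo	chymotrypsin	127C	0	3
plex_chymo	chymotrypsin	128N	0	4
plex_chymo	chymotrypsin	128C	2	1
plex_chymo	chymotrypsin	129N	2	2
plex_chymo	chymotrypsin	129C	2	3
plex_chymo	chymotrypsin	130N	2	4
plex_chymo	chymotrypsin	130C	6	1
plex_chymo	chymotrypsin	131N	6	2
plex_chymo	chymotrypsin	131C	6	3
plex_chymo	chymotrypsin	132N	6	4
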