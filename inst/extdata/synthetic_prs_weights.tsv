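variant_id	effect_allele	log_or
rs0822905	G	0.176178
rs0018726	C	0.228133
rs0788079	A	0.234607
rs0711788	T	0.034542
rs0234672	T	0.289734
rs0307487	C	0.082847
rs0776506	C	0.111968
rs0088920	A	0.274246
rs0131151	T	0.187976
rs0787566	A	0.157275
rs0022508	A	0.141347
rs0593846	A	0.046303
rs0077694	T	0.2054
rs0074717	A	0.159975
rs0301580	A	0.189698
rs0470245	A	0.21393
rs0984099	C	0.269806
rs0748803	A	0.135448
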