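group	stratum	ca_class	n_genomes_total	n_genomes_with_ca
all	all	all	24184	16892
all	all	alpha	24184	3598
all	all	beta	24184	13738
all	all	gamma	24184	14010
Bacteria	all	all	21953	15090
Archaea	all	all	767	370
Fungi	all	all	1269	1250
Algae	all	all	291	91
Bacteria	cultured	all	14333	12255
Archaea	cultured	all	297	245
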