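name	seq	length_bases	start	end	orientation	role
hsp70-U7F	CGTGCAGTCGGTATCGACCTCGGBACVACBAACTC	35	7	41	sense	amplification
hsp70-1326R	CGATGCCGTTGGCGTCGATGTCGAASGHSACCTCGA	36	1326	1363	antisense	amplification
U1F	CGTGCAGTCGGTATCGACCTCGG	23	7	29	sense	sequencing
2R	CGATGCCGTTGGCGTCGATGTC	22	1326	1347	antisense	sequencing
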