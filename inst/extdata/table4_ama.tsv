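# Verbatim transcription of the reciprocal chromosome painting summary
# between Myiopsitta monachus (MMO) and Ara macao (AMA), with the chicken
# (GGA) content of each correspondence. The probe side here is MMO
# (species-local), so this table is NOT a homology-map TSV consumable by
# parse_homology_tsv(); it is shipped for provenance and documentation.
# Cell text is kept exactly as printed.
mmo_chr	gga	ama_chr
2, Z	2q, Z	2q, Z
1	4q, 4p,14,23,25,28	1p,8q + 4 micros
2, 3, 4, Z	2p/q,1p/q, Z, micros	1q,2q/p,4q,Z, micros
4	1p	1q
5,6	3p/q,5	3q,5q
5,6,7,8	3p/q,5,8,9	3,5,6,
8,9	7,6,8,9	6,7
7	3q	6
10,11	6,7,10,micro	7,micro
12	1q	4q
13	2p + micro	2p + micro
14,15	1q (MMO14), micro	1q (MMO14), micro
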