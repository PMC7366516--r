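# SYNTHETIC outgroup row: Turdus rufiventris (TRU, 2n = 78). The published
# syntenic-group table does not include the thrush outgroup, so this file
# encodes the conserved passerine-like karyotype (one-to-one with the
# chicken macrochromosomes, GGA4 arms on separate chromosomes) as a
# stand-in reconstruction. It is NOT a transcription of published painting
# data and is used only for the reconstructed demonstration matrix and
# smoke tests.
taxon	ancestral_chr	ancestral_region	descendant_chr	descendant_region	evidence	diploid_number	provenance
TRU	GGA1	whole	TRU1	whole	inferred	78	synthetic identity row
TRU	GGA2	whole	TRU2	whole	inferred	78	synthetic identity row
TRU	GGA3	whole	TRU3	whole	inferred	78	synthetic identity row
TRU	GGA4	q	TRU4	whole	inferred	78	synthetic identity row
TRU	GGA5	whole	TRU5	whole	inferred	78	synthetic identity row
TRU	GGA6	whole	TRU6	whole	inferred	78	synthetic identity row
TRU	GGA7	whole	TRU7	whole	inferred	78	synthetic identity row
TRU	GGA8	whole	TRU8	whole	inferred	78	synthetic identity row
TRU	GGA9	whole	TRU9	whole	inferred	78	synthetic identity row
TRU	GGA4	p	TRU10	whole	inferred	78	synthetic identity row
TRU	GGA10	whole	TRU11	whole	inferred	78	synthetic identity row
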