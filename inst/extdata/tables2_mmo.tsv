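# Whole-chromosome painting homology map: chicken (GGA) probes on
# Myiopsitta monachus (MMO), 2n = 48. Transcribed from the published
# correspondence table; the provenance column quotes the source cell.
# The merged source row "PAK11-13 / GGA10-12 / 2 pairs / 9p,11" is encoded
# as GGA10 -> {MMO9p, MMO11} only; GGA11 and GGA12 are left unassigned
# (see README.md).
taxon	ancestral_chr	ancestral_region	descendant_chr	descendant_region	evidence	diploid_number	provenance
MMO	GGA1	whole	MMO3	q	whole-chromosome-paint	48	PAK1 GGA1 4 Pairs 3q,4p/q,12,14q
MMO	GGA1	whole	MMO4	pq	whole-chromosome-paint	48	PAK1 GGA1 4 Pairs 3q,4p/q,12,14q
MMO	GGA1	whole	MMO12	whole	whole-chromosome-paint	48	PAK1 GGA1 4 Pairs 3q,4p/q,12,14q
MMO	GGA1	whole	MMO14	q	whole-chromosome-paint	48	PAK1 GGA1 4 Pairs 3q,4p/q,12,14q
MMO	GGA2	whole	MMO2	whole	whole-chromosome-paint	48	PAK2 GGA2 3 pairs 2,3p,13q
MMO	GGA2	whole	MMO3	p	whole-chromosome-paint	48	PAK2 GGA2 3 pairs 2,3p,13q
MMO	GGA2	whole	MMO13	q	whole-chromosome-paint	48	PAK2 GGA2 3 pairs 2,3p,13q
MMO	GGA3	whole	MMO5	whole	whole-chromosome-paint	48	PAK3 GGA3 2 pairs 5,7
MMO	GGA3	whole	MMO7	whole	whole-chromosome-paint	48	PAK3 GGA3 2 pairs 5,7
MMO	GGA4	q	MMO1	q	whole-chromosome-paint	48	PAK4 GGA4q 2 pairs 1q/7q
MMO	GGA4	q	MMO7	q	whole-chromosome-paint	48	PAK4 GGA4q 2 pairs 1q/7q
MMO	GGA5	whole	MMO6	whole	whole-chromosome-paint	48	PAK5 GGA5 1 pair 6
MMO	GGA6	whole	MMO9	q	whole-chromosome-paint	48	PAK6 GGA6 2 pairs 9q,10q
MMO	GGA6	whole	MMO10	q	whole-chromosome-paint	48	PAK6 GGA6 2 pairs 9q,10q
MMO	GGA7	whole	MMO9	q	whole-chromosome-paint	48	PAK7 GGA7 2 pairs 9q,10q
MMO	GGA7	whole	MMO10	q	whole-chromosome-paint	48	PAK7 GGA7 2 pairs 9q,10q
MMO	GGA8	whole	MMO8	p	whole-chromosome-paint	48	PAK8 GGA8 1 pair 8p
MMO	GGA9	whole	MMO8	q	whole-chromosome-paint	48	PAK9 GGA9 1 pair 8q
MMO	GGA4	p	MMO1	p	whole-chromosome-paint	48	PAK10 GGA4p 2 pair 1p, 7q
MMO	GGA4	p	MMO7	q	whole-chromosome-paint	48	PAK10 GGA4p 2 pair 1p, 7q
MMO	GGA10	whole	MMO9	p	whole-chromosome-paint	48	PAK11-13 GGA10-12 2 pairs 9p,11 (GGA10 portion only)
MMO	GGA10	whole	MMO11	whole	whole-chromosome-paint	48	PAK11-13 GGA10-12 2 pairs 9p,11 (GGA10 portion only)
MMO	GGA13	whole	MMO13	p	whole-chromosome-paint	48	PAK14 GGA13 1 pair 13p
MMO	GGA14	whole	MMO1	p	whole-chromosome-paint	48	PAK15 GGA14 1 pair 1p
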