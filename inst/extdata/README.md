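# Packaged fixtures

Plain-text transcriptions of published comparative chromosome painting
tables for parrots (Psittaciformes), used as worked examples and test
fixtures. Every file is tab-separated UTF-8 with `#` comment lines; the
`provenance` column quotes the source cell so that every transcription
decision is auditable.

| file | contents |
|------|----------|
| `tables2_mmo.tsv` | Chicken (GGA) whole-chromosome probes on *Myiopsitta monachus* (MMO, 2n = 48). |
| `table3_bacs.tsv` | Chicken microchromosome BACs (GGA17–28) on MMO. |
| `table4_ama.tsv` | Reciprocal MMO ↔ *Ara macao* painting summary, verbatim. Probe side is MMO, so this is documentation only, not a parseable homology map. |
| `table5_all_species.tsv` | Syntenic-group correspondences for 11 parrot species plus the chicken identity row, against PAK/GGA. |
| `turdus_synthetic.tsv` | **Synthetic** identity-style outgroup row for *Turdus rufiventris*; not published data (see file header). |

Transcription notes:

- The source table merges PAK11–13 (GGA10–12) into one row while the text
  assigns only GGA10 (MMO9p, MMO11). The fixture encodes GGA10 → {MMO9p,
  MMO11} and leaves GGA11/GGA12 unassigned; characters touching them score
  as missing (`?`) for MMO.
- Where the running text and a table disagree (e.g. the MMO1 content is
  given as GGA4p/q+GGA14+GGA23+GGA25 in the text but with chromosome 28 in
  the reciprocal-painting table), the more specific BAC table wins; the
  provenance column records the source cell in all cases.
- Unidentified microchromosome homologies are written `micro` and are
  excluded from character coding.
- Blank source cells (AMA/GGA10, PER/GGA10) have no row and therefore
  score as missing data.
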