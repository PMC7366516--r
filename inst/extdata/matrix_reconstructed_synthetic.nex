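#NEXUS
[ RECONSTRUCTED demonstration matrix - NOT the published supplementary matrix. ]
[ Auto-coded by karyotree::build_matrix() from table5_all_species.tsv plus the ]
[ synthetic Turdus outgroup row (turdus_synthetic.tsv). Used for smoke tests  ]
[ and report-only comparisons; printed tree statistics of the source study    ]
[ are not reproducible from it.                                               ]
BEGIN DATA;
  DIMENSIONS NTAX=8 NCHAR=17;
  FORMAT DATATYPE=STANDARD SYMBOLS="01" MISSING=? GAP=-;
  CHARLABELS
    'F.PAK1+PAK2' 'F.PAK1+PAK4' 'F.PAK10+PAK3' 'F.PAK10+PAK4' 'F.PAK6+PAK7' 'F.PAK11+PAK6+PAK7' 'F.PAK8+PAK9' 'S.PAK1.ge2' 'S.PAK1.ge3' 'S.PAK1.ge4' 'S.PAK2.ge2' 'S.PAK2.ge3' 'S.PAK3.ge2' 'S.PAK6.ge2' 'S.PAK7.ge2' 'S.PAK10.ge2' 'S.PAK11.ge2';
  MATRIX
    GGA          00010000000000000
    AHY          01001011000000000
    ACH          01001011001000010
    PFR          01001001000000000
    AMA          01001?1110000000?
    MMO          10111111111111111
    AAE          00001001001000000
    TRU          00000000000000000
  ;
END;
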