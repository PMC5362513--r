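# AR ligand-binding-domain hotspot loci interrogated by the assay panel.
# AR is on the plus strand of chromosome X, so codon notation is in genomic
# orientation. Positions are illustrative placeholders (the analysis keys on
# locus_id and never performs genome lookups).
loci:
  - gene: AR
    locus_id: L702H
    chrom: chrX
    position: 66931244
    ref: T
    alts: [A]
    notation: "CtC>CaC"
    orientation: genomic
  - gene: AR
    locus_id: W742C
    chrom: chrX
    position: 66931364
    ref: G
    alts: [T, C]
    notation: "TGg>TGt/c"
    orientation: genomic
  - gene: AR
    locus_id: H875Y
    chrom: chrX
    position: 66943543
    ref: C
    alts: [T]
    notation: "cAT>tAT"
    orientation: genomic
  - gene: AR
    locus_id: F877L
    chrom: chrX
    position: 66943549
    ref: T
    alts: [C]
    notation: "tTC>cTC"
    orientation: genomic
  - gene: AR
    locus_id: T878A
    chrom: chrX
    position: 66943552
    ref: A
    alts: [G]
    notation: "aCT>gCT"
    orientation: genomic
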