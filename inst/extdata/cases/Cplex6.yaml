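# Chromoanasynthesis insertion with a DUP-TRP/INV-DUP pattern on chrX: a
# 6 kb triplication embedded, inverted, inside a 70 kb duplication, plus a
# chr5 duplication inserted in inverted orientation. Two junctions were
# sequenced; a third joining the distal sides of the triplication and the
# chrX duplication is required to complete the derivative and is inferred
# as hypothetical ('??'). The 376 bp templated insert at Jct2 is copied
# from three loci on chr5 and chrX. The chr5 dup scales 0.58 Mb -> 5.8 kb;
# the chrX dup (70 kb) and embedded trp (6 kb) keep their printed sizes.
case_id: Cplex6
kind: rearrangement
genome:
  chromosomes:
    - {name: chrX, length: 250000, ploidy: 2}
    - {name: chr5, length: 100000, ploidy: 2}
recipient: chrX
calls:
  - {chrom: chrX, start: 100001, end: 132000, type: DUP}
  - {chrom: chrX, start: 132001, end: 138000, type: TRP}
  - {chrom: chrX, start: 138001, end: 170000, type: DUP}
  - {chrom: chr5, start: 20001, end: 25800, type: DUP}
junctions:
  - id: Jct1
    support: sequenced
    a: {chrom: chr5, pos: 20001, side: retains_right}
    b: {chrom: chrX, pos: 100001, side: retains_right}
    feature: {kind: blunt}
    repeat_distal: AluSx1
    repeat_proximal: HERVH-int (in LCR)
  - id: Jct2
    support: sequenced
    a: {chrom: chr5, pos: 25800, side: retains_left}
    b: {chrom: chrX, pos: 132001, side: retains_right}
    feature:
      kind: templated_insertion
      parts:
        - {chrom: chr5, start: 30001, end: 30150, strand: "+"}
        - {chrom: chrX, start: 90001, end: 90126, strand: "+"}
        - {chrom: chr5, start: 40001, end: 40100, strand: "+"}
    repeat_distal: "-"
    repeat_proximal: "-"
metadata:
  de_novo: "unknown"
expected:
  ins_string: "ins(X;5)(q28;p15.3p15.3)"
  cnv_description: "Xq28 DUP-TRP/INV-DUP, 5p15.33 DUP"
  pattern: {chrX: DUP-TRP-DUP, chr5: DUP}
  junction_features: ["blunt ends", "376bp templated insertion"]
  templated_insert_len: 376
  n_junctions_total: 3
  n_junctions_sequenced: 2
  n_hypothetical: 1
  hypothetical_junction:
    a: {chrom: chrX, pos: 138000, side: retains_left}
    b: {chrom: chrX, pos: 170000, side: retains_left}
  dup_trp_inv_dup: true
  trp_size: 6000
  dup_region_size: 70000
  classification: chromoanasynthesis
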