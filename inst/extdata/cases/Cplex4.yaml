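# Basic complex insertion: one duplicated fragment of chr14 inserted, in
# direct orientation, into a deletion on chr13. Toy coordinates: Mb-scale
# printed sizes are scaled down 100x (11.8 Mb dup -> 118 kb, 4.4 Mb del ->
# 44 kb); junction features and repeat labels transcribed as printed.
case_id: Cplex4
kind: rearrangement
genome:
  chromosomes:
    - {name: chr13, length: 300000, ploidy: 2}
    - {name: chr14, length: 400000, ploidy: 2}
recipient: chr13
calls:
  - {chrom: chr13, start: 100001, end: 144000, type: DEL}
  - {chrom: chr14, start: 150001, end: 268000, type: DUP}
junctions:
  - id: Jct1
    support: sequenced
    a: {chrom: chr13, pos: 100000, side: retains_left}
    b: {chrom: chr14, pos: 150001, side: retains_right}
    feature: {kind: microhomology, mh_len: 1}
    repeat_distal: MER44B
    repeat_proximal: "-"
  - id: Jct2
    support: sequenced
    a: {chrom: chr14, pos: 268000, side: retains_left}
    b: {chrom: chr13, pos: 144001, side: retains_right}
    feature: {kind: microhomology, mh_len: 1}
    repeat_distal: MER113B
    repeat_proximal: L2a
metadata:
  de_novo: "no"
expected:
  ins_string: "ins(13;14)(q21.31;q22.3q24.1)"
  cnv_description: "14q22.3q24.1 DUP, 13q21.31q21.32 DEL"
  pattern: {chr13: DEL, chr14: DUP}
  junction_features: ["1bp MH", "1bp MH"]
  n_junctions_total: 2
  n_junctions_sequenced: 2
  n_hypothetical: 0
  inserted_inverted: false
  dup_trp_inv_dup: false
  classification: basic_complex_insertion
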