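# Chromoanasynthesis insertion on chr6 + chrX. The chrX duplication is
# inserted into the first chr6 deletion, and the chr6q-proximal
# duplication into the second deletion, giving the chr6 pattern
# DUP-NML-DEL-NML-DEL. Four sequenced junctions, no hypothetical junction
# needed. Toy coordinates scale Mb-scale printed sizes 100x down
# (1.3 Mb -> 13 kb, 0.4 Mb -> 4 kb, 8.6 Mb -> 86 kb, 1.5 Mb -> 15 kb).
case_id: Cplex5
kind: rearrangement
genome:
  chromosomes:
    - {name: chr6, length: 300000, ploidy: 2}
    - {name: chrX, length: 200000, ploidy: 2}
recipient: chr6
calls:
  - {chrom: chr6, start: 50001, end: 63000, type: DUP}
  - {chrom: chr6, start: 100001, end: 104000, type: DEL}
  - {chrom: chr6, start: 150001, end: 236000, type: DEL}
  - {chrom: chrX, start: 80001, end: 95000, type: DUP}
junctions:
  - id: Jct1
    support: sequenced
    a: {chrom: chr6, pos: 100000, side: retains_left}
    b: {chrom: chrX, pos: 80001, side: retains_right}
    feature:
      kind: templated_insertion
      parts:
        - {chrom: chrX, start: 79900, end: 79906, strand: "+"}
    repeat_distal: HERVH48-int
    repeat_proximal: in LCR
  - id: Jct2
    support: sequenced
    a: {chrom: chrX, pos: 95000, side: retains_left}
    b: {chrom: chr6, pos: 104001, side: retains_right}
    feature: {kind: microhomology, mh_len: 2}
    repeat_distal: L2a (in LCR)
    repeat_proximal: "-"
  - id: Jct3
    support: sequenced
    a: {chrom: chr6, pos: 150000, side: retains_left}
    b: {chrom: chr6, pos: 50001, side: retains_right}
    feature: {kind: microhomology, mh_len: 5}
    repeat_distal: MER102a
    repeat_proximal: "-"
  - id: Jct4
    support: sequenced
    a: {chrom: chr6, pos: 63000, side: retains_left}
    b: {chrom: chr6, pos: 236001, side: retains_right}
    feature: {kind: microhomology, mh_len: 2}
    repeat_distal: "-"
    repeat_proximal: "-"
metadata:
  de_novo: "yes"
expected:
  ins_string: "ins(6;X)(q25.3;q28q28)"
  cnv_description: "6q21q25.3 DUP-NML-DEL-NML-DEL, Xq28 DUP"
  pattern: {chr6: DUP-NML-DEL-NML-DEL, chrX: DUP}
  junction_features: ["7bp templated insertion", "2bp MH", "5bp MH", "2bp MH"]
  n_junctions_total: 4
  n_junctions_sequenced: 4
  n_hypothetical: 0
  dup_trp_inv_dup: false
  classification: chromoanasynthesis
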