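# Basic complex insertion: a duplicated fragment of chr9 inserted, in
# inverted orientation, into a deletion on chr13. Toy coordinates scale
# the printed 2.2 Mb dup to 22 kb and the 8.3 Mb del to 83 kb.
case_id: Cplex9
kind: rearrangement
genome:
  chromosomes:
    - {name: chr13, length: 300000, ploidy: 2}
    - {name: chr9, length: 200000, ploidy: 2}
recipient: chr13
calls:
  - {chrom: chr13, start: 100001, end: 183000, type: DEL}
  - {chrom: chr9, start: 50001, end: 72000, type: DUP}
junctions:
  - id: Jct1
    support: sequenced
    a: {chrom: chr13, pos: 100000, side: retains_left}
    b: {chrom: chr9, pos: 72000, side: retains_left}
    feature: {kind: microhomology, mh_len: 2}
    repeat_distal: "-"
    repeat_proximal: "-"
  - id: Jct2
    support: sequenced
    a: {chrom: chr9, pos: 50001, side: retains_right}
    b: {chrom: chr13, pos: 183001, side: retains_right}
    feature: {kind: microhomology, mh_len: 3}
    repeat_distal: AluSq
    repeat_proximal: "-"
metadata:
  de_novo: "no"
expected:
  ins_string: "ins(13;9)(q12.3;q21.31q21.31)"
  cnv_description: "9q21.31 DUP, 13q12.3q13.3 DEL"
  pattern: {chr13: DEL, chr9: DUP}
  junction_features: ["2bp MH", "3bp MH"]
  n_junctions_total: 2
  n_junctions_sequenced: 2
  n_hypothetical: 0
  inserted_inverted: true
  dup_trp_inv_dup: false
  classification: basic_complex_insertion
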