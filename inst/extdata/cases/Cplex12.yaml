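# Basic complex insertion: a duplicated fragment of chr6 inserted, in
# inverted orientation, into a deletion on chr5; both junctions carry
# small untemplated inserts. Toy coordinates scale the printed 0.8 Mb dup
# to 8 kb and the 0.5 Mb del to 5 kb.
case_id: Cplex12
kind: rearrangement
genome:
  chromosomes:
    - {name: chr5, length: 200000, ploidy: 2}
    - {name: chr6, length: 150000, ploidy: 2}
recipient: chr5
calls:
  - {chrom: chr5, start: 80001, end: 85000, type: DEL}
  - {chrom: chr6, start: 100001, end: 108000, type: DUP}
junctions:
  - id: Jct1
    support: sequenced
    a: {chrom: chr5, pos: 80000, side: retains_left}
    b: {chrom: chr6, pos: 108000, side: retains_left}
    feature: {kind: untemplated_insertion, insert_seq: CA}
    repeat_distal: "-"
    repeat_proximal: "-"
  - id: Jct2
    support: sequenced
    a: {chrom: chr6, pos: 100001, side: retains_right}
    b: {chrom: chr5, pos: 85001, side: retains_right}
    feature: {kind: untemplated_insertion, insert_seq: TGA}
    repeat_distal: MER5B
    repeat_proximal: L2a
metadata:
  de_novo: "no"
expected:
  ins_string: "ins(5;6)(p14.3;q27q27)"
  cnv_description: "6p27 DUP, 5p14.3 DEL"
  pattern: {chr5: DEL, chr6: DUP}
  junction_features: ["2bp insertion", "3bp insertion"]
  n_junctions_total: 2
  n_junctions_sequenced: 2
  n_hypothetical: 0
  inserted_inverted: true
  dup_trp_inv_dup: false
  classification: basic_complex_insertion
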