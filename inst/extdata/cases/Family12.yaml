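# Family 12: an intrachromosomal insertion from the chr19 long arm into
# the short arm in the mother (Mat12), apparently balanced by FISH but
# carrying small duplications at both boundaries of the moved region.
# Labelling the rearranged q-arm interval a-b-c-d: the inserted p-arm
# block carries one extra copy of a, c and d and two of b, while the
# q arm lost b and c; the mother's array therefore shows duplications of
# a, b and d and neutral c (her duplicated b is a triplication plus a
# deletion adding up). Homologous recombination between the rearranged
# and the intact chr19 gave her daughter (P12_dup) a ~3.5 Mb duplication
# with an embedded ~33 kb triplication (segment b) and her son (P12_del)
# the slightly smaller reciprocal deletion (b+c). Mb/kb printed sizes are
# scaled 100x: dup 3.5 Mb -> 35 kb, boundary dups 111 kb -> 1,110 bp and
# 77 kb -> 770 bp, trp 33 kb -> 330 bp.
case_id: Family12
kind: family
insertion_type: intrachromosomal
genome:
  chromosomes:
    - {name: chr19, length: 300000, ploidy: 2}
parent:
  id: Mat12
  derivatives:
    - recipient: chr19
      walk:
        - {chrom: chr19, start: 1, end: 50000, strand: "+"}
        - {chrom: chr19, start: 200001, end: 201110, strand: "+"}  # a
        - {chrom: chr19, start: 201111, end: 201440, strand: "+"}  # b
        - {chrom: chr19, start: 201111, end: 201440, strand: "+"}  # b again
        - {chrom: chr19, start: 201441, end: 234230, strand: "+"}  # c
        - {chrom: chr19, start: 234231, end: 235000, strand: "+"}  # d
        - {chrom: chr19, start: 50001, end: 200000, strand: "+"}
        - {chrom: chr19, start: 200001, end: 201110, strand: "+"}  # a in place
        - {chrom: chr19, start: 234231, end: 235000, strand: "+"}  # d in place
        - {chrom: chr19, start: 235001, end: 300000, strand: "+"}
  calls:
    - {chrom: chr19, start: 200001, end: 201440, type: DUP}  # a+b
    - {chrom: chr19, start: 234231, end: 235000, type: DUP}  # d
junctions:
  - id: Mat12_DEL_Jct
    support: sequenced
    a: {chrom: chr19, pos: 201110, side: retains_left}
    b: {chrom: chr19, pos: 234231, side: retains_right}
    feature: {kind: untemplated_insertion, insert_seq: ACGTTGCAATCGGATCCA}
    repeat_distal: AluY
    repeat_proximal: AluY (in LCR)
children:
  - id: P12_dup
    affected: true
    transmitted: {chr19: recombinant}
    calls:
      - {chrom: chr19, start: 200001, end: 201110, type: DUP}
      - {chrom: chr19, start: 201111, end: 201440, type: TRP}
      - {chrom: chr19, start: 201441, end: 235000, type: DUP}
  - id: P12_del
    affected: true
    transmitted: {chr19: recombinant}
    calls:
      - {chrom: chr19, start: 201111, end: 234230, type: DEL}
metadata:
  de_novo: "unknown"
expected:
  ins_string: "ins(19)(p13;q13.33q13.33)"
  cnv_description: "19q13.33 DUP, 19q13.31 DUP"
  junction_features: ["18bp insertion"]
  pattern_parent: {chr19: DUP-NML-DUP}
  child_dup_pattern: DUP-TRP-DUP
  child_del_pattern: DEL
  classification: unclassified
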