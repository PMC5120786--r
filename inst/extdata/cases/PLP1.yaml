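# The proteolipid-protein-gene deletion/insertion family: the mother
# carries an apparently balanced insertion of a chrX segment into chr19
# that is not balanced at the molecular level - a 10 kb deletion and a
# 22 kb duplication flank the inserted fragment on chrX, and a 182 kb
# duplication marks the insertion site on chr19 (kb-scale printed sizes
# kept as printed). Her affected son inherited the deleted chrX with an
# intact chr19; her unaffected son inherited an intact chrX and the chr19
# carrying the insertion. Junction 3 (the deletion junction) is on the
# derivative chrX; Junctions 1 and 2 are on the derivative chr19.
case_id: PLP1
kind: family
insertion_type: interchromosomal
genome:
  chromosomes:
    - {name: chrX, length: 200000, ploidy: 2}
    - {name: chr19, length: 400000, ploidy: 2}
parent:
  id: BAB1381
  derivatives:
    - recipient: chrX
      walk:
        - {chrom: chrX, start: 1, end: 60000, strand: "+"}
        - {chrom: chrX, start: 100001, end: 200000, strand: "+"}
    - recipient: chr19
      walk:
        - {chrom: chr19, start: 1, end: 282000, strand: "+"}
        - {chrom: chrX, start: 70001, end: 122000, strand: "+"}
        - {chrom: chr19, start: 100001, end: 400000, strand: "+"}
  calls:
    - {chrom: chrX, start: 60001, end: 70000, type: DEL}
    - {chrom: chrX, start: 100001, end: 122000, type: DUP}
    - {chrom: chr19, start: 100001, end: 282000, type: DUP}
junctions:
  - id: Jct1
    support: sequenced
    a: {chrom: chr19, pos: 282000, side: retains_left}
    b: {chrom: chrX, pos: 70001, side: retains_right}
    feature: {kind: microhomology, mh_len: 3}
    repeat_distal: L2a
    repeat_proximal: AluSx3
  - id: Jct2
    support: sequenced
    a: {chrom: chrX, pos: 122000, side: retains_left}
    b: {chrom: chr19, pos: 100001, side: retains_right}
    feature:
      kind: templated_insertion
      parts:
        - {chrom: chr19, start: 99900, end: 99914, strand: "+"}
    repeat_distal: AluSg4
    repeat_proximal: L1PA3
  - id: Jct3
    support: sequenced
    a: {chrom: chrX, pos: 60000, side: retains_left}
    b: {chrom: chrX, pos: 100001, side: retains_right}
    feature: {kind: microhomology, mh_len: 18}
    repeat_distal: AluSx1
    repeat_proximal: AluSz
children:
  - id: BAB1379
    affected: true
    child_baseline: {chrX: 1, chr19: 2}
    transmitted: {chrX: derivative, chr19: intact}
    calls:
      - {chrom: chrX, start: 60001, end: 100000, type: DEL}
  - id: BAB1380
    affected: false
    child_baseline: {chrX: 1, chr19: 2}
    transmitted: {chrX: intact, chr19: derivative}
    calls:
      - {chrom: chrX, start: 70001, end: 122000, type: DUP}
      - {chrom: chr19, start: 100001, end: 282000, type: DUP}
metadata:
  de_novo: "unknown"
expected:
  ins_string: "ins(19;X)(q22.2;q13.4q13.4)"
  cnv_description: "Xq22.2 DEL-NML-DUP, 19q13.4 DUP"
  junction_features: ["3bp MH", "15bp templated insertion", "18bp MH"]
  pattern_parent: {chrX: DEL-NML-DUP, chr19: DUP}
  n_outcomes: 4
  classification: chromoanasynthesis
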