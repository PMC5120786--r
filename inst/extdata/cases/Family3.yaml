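# Family 3: a bidirectional, mostly balanced exchange of genetic material
# between chr7 and chr9 in the mother (Mat3). The 4.588 Mb chr7 fragment
# (scaled 100x to 45,880 bp) moved into chr9, breaking and re-joining in
# the process; an 815 bp fragment from chr9 (printed coordinates
# chr9:5874574-5875388 preserved verbatim) moved into the chr7 deletion
# junction. Only a 4 kb deletion at the distal boundary of the moved chr7
# fragment remains in the mother. Her child P3 inherited the deleted chr7
# (with the 815 bp chr9 insertion) and an intact chr9. One junction
# connecting the inserted chr7 material to chr9 could not be mapped and
# is carried as hypothetical. Coordinate-only genome: junction features
# are transcribed, not recomputed from sequence.
case_id: Family3
kind: family
insertion_type: interchromosomal
genome:
  chromosomes:
    - {name: chr7, length: 600000, ploidy: 2}
    - {name: chr9, length: 6000000, ploidy: 2}
parent:
  id: Mat3
  derivatives:
    - recipient: chr7
      walk:
        - {chrom: chr7, start: 1, end: 200000, strand: "+"}
        - {chrom: chr9, start: 5874574, end: 5875388, strand: "+"}
        - {chrom: chr7, start: 245881, end: 600000, strand: "+"}
    - recipient: chr9
      walk:
        - {chrom: chr9, start: 1, end: 5874573, strand: "+"}
        - {chrom: chr7, start: 220001, end: 241880, strand: "+"}
        - {chrom: chr7, start: 200001, end: 220000, strand: "+"}
        - {chrom: chr9, start: 5875389, end: 6000000, strand: "+"}
  calls:
    - {chrom: chr7, start: 241881, end: 245880, type: DEL}
junctions:
  - id: Jct1
    support: sequenced
    a: {chrom: chr7, pos: 200000, side: retains_left}
    b: {chrom: chr7, pos: 245881, side: retains_right}
    feature:
      kind: templated_insertion
      parts:
        - {chrom: chr9, start: 5874574, end: 5875388, strand: "+"}
    repeat_distal: "-"
    repeat_proximal: HERVK14-int
  - id: Jct2
    support: sequenced
    a: {chrom: chr7, pos: 241880, side: retains_left}
    b: {chrom: chr7, pos: 200001, side: retains_right}
    feature:
      kind: templated_insertion
      parts:
        - {chrom: chr7, start: 199900, end: 199905, strand: "+"}
    repeat_distal: HERVK14-int
    repeat_proximal: MIR3
  - id: Jct3
    support: sequenced
    a: {chrom: chr7, pos: 220000, side: retains_left}
    b: {chrom: chr9, pos: 5875389, side: retains_right}
    feature: {kind: microhomology, mh_len: 6}
    repeat_distal: MER21A
    repeat_proximal: "-"
  - id: JctH
    support: hypothetical
    a: {chrom: chr9, pos: 5874573, side: retains_left}
    b: {chrom: chr7, pos: 220001, side: retains_right}
children:
  - id: P3
    affected: true
    transmitted: {chr7: derivative, chr9: intact}
    calls:
      - {chrom: chr7, start: 200001, end: 245880, type: DEL}
      - {chrom: chr9, start: 5874574, end: 5875388, type: DUP}
metadata:
  de_novo: "unknown"
expected:
  ins_string: "ins(9;7)(p24;p15.1p15.1)"
  cnv_description: "7p15.1 DEL"
  junction_features: ["815bp templated insertion", "6bp templated insertion", "6bp MH"]
  insert_815_interval: {chrom: chr9, start: 5874574, end: 5875388}
  insert_815_len: 815
  n_outcomes: 4
  classification: balanced_end_joining_exchange
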