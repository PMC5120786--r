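# The most complex case: a rearranged chr13 with multiple inserted chrX
# fragments, a DUP-NML-DUP-NML-DEL pattern on chr13 and a
# DUP-NML-DUP-TRP-DUP pattern on chrX. Five junctions were sequenced; the
# sixth (Junction 5, joining the proximal side of the second chr13
# duplication to the proximal side of the second chrX duplication) is
# hypothetical. Jct2 carries a templated insertion listed as 13,357 bp as
# printed, while its two parts (8,192 bp + 5,167 bp, the second from a
# third chromosome) sum to 13,359 bp; the discrepancy is preserved
# as printed and flagged, not reconciled. Part lengths are exact printed
# values; flanking sizes are toy scale.
case_id: Cplex11
kind: rearrangement
genome:
  chromosomes:
    - {name: chr13, length: 400000, ploidy: 2}
    - {name: chrX, length: 300000, ploidy: 2}
    - {name: chr4, length: 100000, ploidy: 2}
recipient: chr13
calls:
  - {chrom: chr13, start: 100001, end: 120000, type: DUP}
  - {chrom: chr13, start: 140001, end: 160000, type: DUP}
  - {chrom: chr13, start: 200001, end: 250000, type: DEL}
  - {chrom: chrX, start: 50001, end: 70000, type: DUP}
  - {chrom: chrX, start: 100001, end: 110000, type: DUP}
  - {chrom: chrX, start: 110001, end: 116000, type: TRP}
  - {chrom: chrX, start: 116001, end: 130000, type: DUP}
junctions:
  - id: Jct1
    support: sequenced
    a: {chrom: chr13, pos: 250001, side: retains_right}
    b: {chrom: chr13, pos: 100001, side: retains_right}
    feature: {kind: blunt}
    repeat_distal: "-"
    repeat_proximal: L1PB1
  - id: Jct2
    support: sequenced
    a: {chrom: chr13, pos: 120000, side: retains_left}
    b: {chrom: chrX, pos: 50001, side: retains_right}
    feature:
      kind: templated_insertion
      parts:
        - {chrom: chrX, start: 10001, end: 18192, strand: "+"}
        - {chrom: chr4, start: 5001, end: 10167, strand: "+"}
      printed_total: 13357
    repeat_distal: "-"
    repeat_proximal: "-"
  - id: Jct3
    support: sequenced
    a: {chrom: chrX, pos: 70000, side: retains_left}
    b: {chrom: chrX, pos: 110001, side: retains_right}
    feature: {kind: blunt}
    repeat_distal: L1MA2
    repeat_proximal: L1PB3
  - id: Jct4
    support: sequenced
    a: {chrom: chr13, pos: 160000, side: retains_left}
    b: {chrom: chrX, pos: 116000, side: retains_left}
    feature: {kind: blunt}
    repeat_distal: L1MC4a
    repeat_proximal: THE1D-int
  - id: Jct6
    support: sequenced
    a: {chrom: chr13, pos: 200000, side: retains_left}
    b: {chrom: chrX, pos: 130000, side: retains_left}
    feature: {kind: microhomology, mh_len: 2}
    repeat_distal: L1MEc
    repeat_proximal: "-"
metadata:
  de_novo: "yes"
expected:
  ins_string: "ins(13;X)(q33.3;q21.1q21.1)"
  cnv_description: "13q33.2q34 DUP-NML-DUP-NML-DEL, Xq21.1 DUP-NML-DUP-TRP-DUP"
  pattern: {chr13: DUP-NML-DUP-NML-DEL, chrX: DUP-NML-DUP-TRP-DUP}
  junction_features: ["blunt ends", "13,357bp templated insertion", "blunt ends",
                      "blunt ends", "2bp MH"]
  templated_parts_bp: [8192, 5167]
  templated_printed_total: 13357
  n_junctions_total: 6
  n_junctions_sequenced: 5
  n_hypothetical: 1
  hypothetical_junction:
    a: {chrom: chr13, pos: 140001, side: retains_right}
    b: {chrom: chrX, pos: 100001, side: retains_right}
  n_chromosomes: 3
  # the chrX triplication sits inverted inside the d-e-f duplication run
  # (inverted Jct4 at its distal boundary), so the structural
  # DUP-TRP/INV-DUP test fires on chrX as well
  dup_trp_inv_dup: true
  classification: chromoanasynthesis
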