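test_that("annotation recovers simulated junction features exactly", {
  for (seed in 1:12) {
    case <- rep_case(seed)
    reads <- emit_junction_reads(case$truth, flank_bp = 300)
    ann <- annotate_junctions(reads, case$genome)
    for (tj in case$truth$junctions) {
      expect_same_junction(ann[[tj$id]], tj)
    }
  }
})

test_that("measured microhomology equals the brute-force overlap oracle", {
  for (seed in 1:12) {
    case <- rep_case(seed)
    for (tj in case$truth$junctions) {
      m <- measure_microhomology(tj$a, tj$b, case$genome)
      expect_identical(m, oracle_mh(tj$a, tj$b, case$genome))
      if (tj$feature$kind == "microhomology") {
        # the flank-shared tract is at least the constructed microhomology
        # (homopolymer edges can extend it beyond the anchor overlap)
        expect_gte(m, tj$feature$mh_len)
      }
    }
  }
  # worked microexample: flanks engineered to share exactly one base
  g <- genome_ref(sequences = c(
    chr1 = paste0(strrep("ACGT", 20), "GGATCCTTAGGCATCAATCGT",
                  strrep("TGCA", 20))))
  a <- breakend("chr1", 80, "retains_left")    # flank ends ...ACGT
  b <- breakend("chr1", 95, "retains_right")
  expect_identical(measure_microhomology(a, b, g), oracle_mh(a, b, g))
})

test_that("annotation is invariant under reverse complement of the read", {
  case <- rep_case(3)
  reads <- emit_junction_reads(case$truth, flank_bp = 300)
  for (id in names(reads)) {
    j1 <- annotate_junction(reads[[id]], case$genome, id = id)
    j2 <- annotate_junction(revcomp(reads[[id]]), case$genome, id = id)
    expect_identical(format(j1$a), format(j2$a))
    expect_identical(format(j1$b), format(j2$b))
    expect_true(same_junction(j1, j2))
    # idempotence on the identical read
    j3 <- annotate_junction(reads[[id]], case$genome, id = id)
    expect_identical(format(j1), format(j3))
  }
})

test_that("microhomology and insert are mutually exclusive in every annotation", {
  for (seed in c(2, 4, 6)) {
    case <- rep_case(seed)
    ann <- annotate_junctions(emit_junction_reads(case$truth, 300), case$genome)
    for (j in ann) {
      f <- j$feature
      has_ins <- nzchar(f$insert_seq) || !is.null(f$template_parts)
      expect_false(f$mh_len > 0 && has_ins)
    }
  }
})

test_that("reference-collinear reads are rejected as junction-free", {
  g <- tiny_genome()
  expect_error(locate_breakends(genome_seq(g, "chr1", 5000, 5400), g),
               "no junction found")
  # reverse-complement collinear read likewise
  expect_error(locate_breakends(genome_seq(g, "chr1", 5000, 5400, "-"), g),
               "no junction found")
})

test_that("repeat-ambiguous anchors raise an ambiguity error listing candidates", {
  g <- make_toy_genome(1, 30000, 0.5, seed = 9)
  s <- g$sequences[["chr1"]]
  substr(s, 10000, 10299) <- substr(s, 1000, 1299)  # duplicate block (toy LCR)
  g2 <- genome_ref(sequences = c(chr1 = s))
  read <- paste0(substr(s, 1100, 1299), substr(s, 20000, 20199))
  err <- tryCatch(locate_breakends(read, g2), insmech_ambiguous = function(e) e)
  expect_s3_class(err, "insmech_ambiguous")
  expect_match(conditionMessage(err), "chr1:")
  j <- annotate_junction(read, g2, id = "lcr")
  expect_true(j$unresolved)
  expect_null(j$feature)
  expect_equal(j$support, "sequenced")
})

test_that("short middles with no genomic source are untemplated insertions", {
  truth <- cached("untemp_truth", {
    g <- make_toy_genome(2, c(40000, 30000), 0.41, seed = 31)
    chain <- event_chain(
      list(chrom = "chr1", pos = 12000),
      list(switch_event("chr2", 8000, "direct", seg_len = 500,
                        untemplated_insert = "TTG"),
           switch_event("chr1", 13000, "direct")),
      list(chrom = "chr1", pos = 13000))
    simulate_replicative(g, chain)
  })
  ann <- annotate_junctions(emit_junction_reads(truth, 300), truth$genome)
  f <- ann[["J1"]]$feature
  expect_equal(f$kind, "untemplated_insertion")
  expect_equal(nchar(f$insert_seq), 3)
  expect_equal(f$mh_len, 0)
})

test_that("a 376 bp middle copied from three loci decomposes into three parts", {
  truth <- cached("templ376_truth", {
    g <- make_toy_genome(3, c(60000, 50000, 40000), 0.41, seed = 21)
    parts <- data.frame(chrom = c("chr2", "chr3", "chr2"),
                        start = c(30001, 20001, 40001),
                        end = c(30150, 20126, 40100),
                        strand = c("+", "+", "-"))
    chain <- event_chain(
      list(chrom = "chr1", pos = 15000),
      list(switch_event("chr2", 5000, "direct", seg_len = 600,
                        templated_insert_sources = parts),
           switch_event("chr1", 16000, "direct")),
      list(chrom = "chr1", pos = 16000))
    simulate_replicative(g, chain)
  })
  ann <- annotate_junctions(emit_junction_reads(truth, 300), truth$genome)
  f <- ann[["J1"]]$feature
  expect_equal(f$kind, "templated_insertion")
  expect_equal(nrow(f$template_parts), 3)
  expect_equal(sum(interval_length(f$template_parts$start, f$template_parts$end)),
               376)
  expect_equal(f$unmatched, 0)
  # parts appear in read order, crossing chromosomes
  expect_equal(f$template_parts$chrom[1:2], c("chr2", "chr3"))
})
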