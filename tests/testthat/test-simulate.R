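test_that("a two-switch chain yields one donor DUP, one acceptor DEL and two junctions", {
  truth <- basic_truth()
  nz <- truth$truth_cnv[truth$truth_cnv$cn != truth$truth_cnv$baseline, ]
  expect_equal(nrow(nz), 2)
  del <- nz[nz$chrom == "chr1", ]
  dup <- nz[nz$chrom == "chr2", ]
  expect_equal(del$cn, 1)
  expect_equal(c(del$start, del$end), c(20001, 21499))
  expect_equal(dup$cn, 3)
  expect_equal(unname(dup$end - dup$start + 1), 800)
  expect_length(truth$junctions, 2)
  expect_equal(truth$junctions[[1]]$feature$kind, "microhomology")
  expect_equal(truth$junctions[[1]]$feature$mh_len, 3)
  expect_equal(truth$junctions[[2]]$feature$kind, "blunt")
})

test_that("a joint with multi-locus templated sources carries all parts in order", {
  g <- make_toy_genome(3, c(60000, 50000, 40000), 0.41, seed = 21)
  parts <- data.frame(chrom = c("chr2", "chr3", "chr2"),
                      start = c(30001, 20001, 40001),
                      end = c(30150, 20126, 40100),
                      strand = c("+", "+", "-"))
  chain <- event_chain(
    start = list(chrom = "chr1", pos = 15000),
    events = list(
      switch_event("chr2", 5000, "direct", seg_len = 600,
                   templated_insert_sources = parts),
      switch_event("chr1", 16000, "direct")
    ),
    resolution = list(chrom = "chr1", pos = 16000), seed = 1)
  truth <- simulate_replicative(g, chain)
  f <- truth$junctions[[1]]$feature
  expect_equal(f$kind, "templated_insertion")
  expect_equal(nrow(f$template_parts), 3)
  expect_equal(sum(interval_length(f$template_parts$start, f$template_parts$end)),
               376)
  expect_equal(f$template_parts$chrom, c("chr2", "chr3", "chr2"))
})

test_that("length conservation and copy-number consistency hold across seeds", {
  for (seed in 1:8) {
    case <- rep_case(seed)
    truth <- case$truth
    d <- truth$derivatives[[1]]
    seg_total <- sum(d$walk$end - d$walk$start + 1)
    ins_total <- sum(vapply(truth$junctions, function(j) {
      if (j$feature$kind == "untemplated_insertion") nchar(j$feature$insert_seq)
      else if (j$feature$kind == "templated_insertion") {
        sum(interval_length(j$feature$template_parts$start,
                            j$feature$template_parts$end))
      } else 0L
    }, numeric(1)))
    mh_total <- sum(vapply(truth$junctions, function(j) j$feature$mh_len,
                           integer(1)))
    expect_equal(nchar(d$seq), seg_total + ins_total - mh_total)

    # brute-force CN oracle at sampled positions: count covering walk
    # segments plus intact homologs
    cnv <- truth$truth_cnv
    set.seed(seed)
    for (chrom in names(truth$genome$lengths)) {
      pos <- sample.int(truth$genome$lengths[[chrom]], 15)
      uses <- vapply(pos, function(p) {
        sum(d$walk$chrom == chrom & d$walk$start <= p & d$walk$end >= p)
      }, numeric(1))
      intact <- truth$genome$ploidy[[chrom]] - (chrom == d$recipient)
      seg <- cnv[cnv$chrom == chrom, ]
      cn_reported <- vapply(pos, function(p) {
        seg$cn[seg$start <= p & seg$end >= p][1]
      }, numeric(1))
      expect_equal(cn_reported, uses + intact)
    }
  }
})

test_that("an unrealizable microhomology joint fails loudly, never silently", {
  g <- make_toy_genome(1, 20000, 0.5, seed = 1)
  chain <- event_chain(list(chrom = "chr1", pos = 5000),
                       list(switch_event("chr1", 9000, "direct", mh_len = 8)),
                       list(chrom = "chr1", pos = 9000))
  expect_error(simulate_replicative(g, chain, engineer = FALSE),
               "joint 1")
  # with engineering enabled the same joint is realized exactly
  truth <- simulate_replicative(g, chain, engineer = TRUE)
  expect_equal(truth$junctions[[1]]$feature$mh_len, 8)
})

test_that("microhomology and inserted sequence are mutually exclusive in events", {
  expect_error(switch_event("chr1", 100, mh_len = 2, untemplated_insert = "AC"),
               "not both")
  expect_error(junction_feature("microhomology", mh_len = 2, insert_seq = "A"))
  expect_error(junction_feature("blunt", mh_len = 1))
})

test_that("end-joining insertion is balanced with at least three junctions", {
  case <- cached("ej_plain", draw_end_joining_case(5))
  truth <- case$truth
  nz <- truth$truth_cnv[truth$truth_cnv$cn != truth$truth_cnv$baseline, ]
  expect_equal(nrow(nz), 0)
  expect_gte(length(truth$junctions), 3)
  for (j in truth$junctions) {
    f <- j$feature
    expect_true(f$kind %in% c("blunt", "microhomology", "untemplated_insertion"))
    expect_lte(f$mh_len, 3)
    expect_lte(nchar(f$insert_seq), 3)
  }
})

test_that("a reciprocal fragment produces a bidirectional balanced exchange", {
  case <- cached("ej_recip", draw_end_joining_case(6, reciprocal = TRUE))
  truth <- case$truth
  nz <- truth$truth_cnv[truth$truth_cnv$cn != truth$truth_cnv$baseline, ]
  expect_equal(nrow(nz), 0)
  expect_length(truth$derivatives, 2)
  expect_length(truth$junctions, 4)
  # donor derivative carries acceptor-chromosome material and vice versa
  don_walk <- truth$derivatives[[2]]$walk
  expect_true(any(don_walk$chrom == truth$derivatives[[1]]$recipient))
  acc_walk <- truth$derivatives[[1]]$walk
  expect_true(any(acc_walk$chrom == truth$derivatives[[2]]$recipient))
})

test_that("flank trimming leaves a small deletion at the donor locus only", {
  case <- cached("ej_trim", draw_end_joining_case(7, trim_bp = 4000))
  nz <- case$truth$truth_cnv[case$truth$truth_cnv$cn != case$truth$truth_cnv$baseline, ]
  expect_equal(nrow(nz), 1)
  expect_equal(nz$cn, 1)
  expect_equal(unname(nz$end - nz$start + 1), 4000)
  expect_equal(nz$chrom, case$truth$derivatives[[2]]$recipient)
})

test_that("probe tables follow the closed-form log2 ratio and are seed-deterministic", {
  truth <- basic_truth()
  tab <- emit_probe_table(truth, spacing_bp = 200, noise_sd = 0)
  dup <- truth$truth_cnv[truth$truth_cnv$cn == 3, ]
  in_dup <- tab$chrom == dup$chrom & tab$pos >= dup$start & tab$pos <= dup$end
  expect_true(all(abs(tab$log2ratio[in_dup] - log2(3 / 2)) < 1e-12))
  del <- truth$truth_cnv[truth$truth_cnv$cn == 1, ]
  in_del <- tab$chrom == del$chrom & tab$pos >= del$start & tab$pos <= del$end
  if (any(in_del)) {
    expect_true(all(abs(tab$log2ratio[in_del] - (-1)) < 1e-12))
  }
  t1 <- emit_probe_table(truth, spacing_bp = 200, noise_sd = 0.15, seed = 5)
  t2 <- emit_probe_table(truth, spacing_bp = 200, noise_sd = 0.15, seed = 5)
  expect_identical(t1, t2)
  expect_error(emit_probe_table(truth, spacing_bp = 10), ">= 50")
})

test_that("junction reads span the joint and skip hypothetical junctions", {
  truth <- basic_truth()
  reads <- emit_junction_reads(truth, flank_bp = 500)
  expect_length(reads, 2)
  expect_equal(unname(nchar(reads)), c(1000, 1000))
  # flipping a junction to hypothetical suppresses its read
  t2 <- basic_truth()
  t2$junctions[[1]]$support <- "hypothetical"
  expect_length(emit_junction_reads(t2, flank_bp = 500), 1)
  # a junction too close to the derivative end yields a truncated read
  g <- make_toy_genome(1, 20000, 0.5, seed = 2)
  chain <- event_chain(list(chrom = "chr1", pos = 300),
                       list(switch_event("chr1", 5000, "direct")),
                       list(chrom = "chr1", pos = 5000))
  tt <- simulate_replicative(g, chain)
  expect_warning(r <- emit_junction_reads(tt, flank_bp = 500), "truncated")
  expect_lt(nchar(r[["J1"]]), 1000)
})
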