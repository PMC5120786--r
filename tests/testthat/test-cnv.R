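test_that("noise-free probe tables recover the simulated copy-number states", {
  truth <- basic_truth()
  # 50 bp spacing: every simulated CNV covers comfortably more than
  # min_probes probes
  tab <- emit_probe_table(truth, spacing_bp = 50, noise_sd = 0)
  segs <- segment_probes(tab, genome = truth$genome)
  calls <- cnv_calls(segs)
  tcalls <- cnv_calls(truth$truth_cnv)
  expect_equal(nrow(calls), nrow(tcalls))
  for (i in seq_len(nrow(tcalls))) {
    m <- calls[calls$chrom == tcalls$chrom[i] & calls$type == tcalls$type[i], ]
    expect_equal(nrow(m), 1)
    expect_lte(abs(m$start - tcalls$start[i]), 50)
    expect_lte(abs(m$end - tcalls$end[i]), 50)
    expect_equal(m$cn, tcalls$cn[i])
  }
})

test_that("noisy segmentation recovers integer CN for CNVs of 20+ probes", {
  for (seed in 1:10) {
    case <- rep_case(seed, n_events = 2, seg_len_range = c(4000, 8000),
                     del_range = c(4000, 8000))
    tab <- emit_probe_table(case$truth, spacing_bp = 200, noise_sd = 0.15,
                            seed = seed)
    calls <- cnv_calls(segment_probes(tab, genome = case$genome))
    tcalls <- cnv_calls(case$truth$truth_cnv)
    expect_equal(nrow(calls), nrow(tcalls))
    for (i in seq_len(nrow(tcalls))) {
      m <- calls[calls$chrom == tcalls$chrom[i] &
                   abs(calls$start - tcalls$start[i]) <= 400, ]
      expect_equal(nrow(m), 1)
      expect_equal(m$cn, tcalls$cn[i])
    }
  }
})

test_that("chromosomes with too few probes fall back to a single baseline segment", {
  probes <- data.frame(chrom = "chr1", pos = c(100, 300, 500),
                       log2ratio = c(0.6, 0.6, 0.6))
  expect_warning(segs <- segment_probes(probes, min_probes = 5), "fewer than")
  expect_equal(nrow(segs), 1)
  expect_equal(segs$cn, 2)
})

test_that("all-baseline input yields an empty CNV list", {
  probes <- data.frame(chrom = "chr1", pos = seq(200, 20000, 200),
                       log2ratio = 0)
  expect_equal(nrow(cnv_calls(segment_probes(probes))), 0)
})

test_that("pattern strings interleave NML across gaps and round-trip", {
  fx5 <- cached("fx_cplex5", load_case_fixture("Cplex5"))
  expect_equal(pattern_string(fx5$calls, "chr6"), "DUP-NML-DEL-NML-DEL")
  expect_equal(pattern_string(fx5$calls, "chrX"), "DUP")
  fx11 <- cached("fx_cplex11", load_case_fixture("Cplex11"))
  expect_equal(pattern_string(fx11$calls, "chr13"), "DUP-NML-DUP-NML-DEL")
  expect_equal(pattern_string(fx11$calls, "chrX"), "DUP-NML-DUP-TRP-DUP")
  expect_equal(pattern_string(fx11$calls, "chr4"), "NML")
  expect_equal(parse_pattern("DUP-NML-DEL-NML-DEL"),
               c("DUP", "NML", "DEL", "NML", "DEL"))
})

test_that("CNV sizes use the closed-interval convention", {
  calls <- cnv_calls(data.frame(chrom = "chr9", start = 5874574, end = 5875388,
                                cn = 3, baseline = 2))
  expect_equal(calls$size_bp, 815)
  expect_equal(interval_length(5874574, 5875388), 815)
})

test_that("DUP-TRP/INV-DUP requires both embedding and an inverted junction", {
  fx6 <- cached("fx_cplex6", load_case_fixture("Cplex6"))
  x_calls <- fx6$calls[fx6$calls$chrom == "chrX", ]
  d <- detect_dup_trp_inv_dup(x_calls, fx6$junctions)
  expect_true(d$detected)
  expect_equal(unname(d$trp$end - d$trp$start + 1), 6000)
  expect_equal(unname(d$dup_region[2] - d$dup_region[1] + 1), 70000)

  # same calls but only direct junctions: no call
  direct <- list(junction("J1", breakend("chrX", 100001, "retains_right"),
                          breakend("chr5", 25800, "retains_left"),
                          feature = junction_feature("blunt")))
  expect_false(detect_dup_trp_inv_dup(x_calls, direct)$detected)

  # TRP without flanking DUPs: no call
  lone_trp <- cnv_calls(data.frame(chrom = "chrX", start = 132001, end = 138000,
                                   cn = 4, baseline = 2))
  expect_false(detect_dup_trp_inv_dup(lone_trp, fx6$junctions)$detected)
})

test_that("a simulated fold-back chain produces a detectable DUP-TRP/INV-DUP", {
  truth <- cached("dtid_truth", {
    g <- make_toy_genome(1, 60000, 0.41, seed = 41)
    # replicate to the distal dup boundary, copy the trp segment inverted,
    # then rejoin at the proximal dup boundary and run to the telomere
    chain <- event_chain(
      list(chrom = "chr1", pos = 30000),
      list(switch_event("chr1", 26000, "inverted", seg_len = 2000),
           switch_event("chr1", 20000, "direct")),
      list(chrom = "chr1", pos = 20000))
    simulate_replicative(g, chain)
  })
  calls <- cnv_calls(truth$truth_cnv)
  expect_equal(pattern_string(calls, "chr1"), "DUP-TRP-DUP")
  d <- detect_dup_trp_inv_dup(calls, truth$junctions)
  expect_true(d$detected)
})

test_that("call tables export both coordinate conventions", {
  calls <- cnv_calls(data.frame(chrom = "chr1", start = 101, end = 200,
                                cn = 3, baseline = 2))
  bed <- tempfile(fileext = ".bed")
  write_calls_bed(calls, bed)
  line <- readLines(bed)[2]
  expect_equal(strsplit(line, "\t")[[1]][2:3], c("100", "200"))
  tsv <- tempfile(fileext = ".tsv")
  write_calls_tsv(calls, tsv)
  expect_match(readLines(tsv)[1], "1-based")
  back <- utils::read.table(tsv, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(back$start, 101)
})
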