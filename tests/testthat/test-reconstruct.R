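test_that("the breakpoint graph assigns role-aware segment multiplicities", {
  fx <- cached("fx_cplex4", load_case_fixture("Cplex4"))
  g <- build_graph(fx$calls, fx$junctions, fx$genome, recipient = "chr13")
  expect_length(g$adjacencies, 2)
  segs <- g$segments
  dup <- segs[segs$chrom == "chr14" & segs$start == 150001, ]
  expect_equal(dup$mult, 1)  # donor DUP: one derivative traversal
  del <- segs[segs$chrom == "chr13" & segs$start == 100001, ]
  expect_equal(del$mult, 0)  # acceptor DEL: never traversed
  nml <- segs[segs$chrom == "chr13" & segs$start == 1, ]
  expect_equal(nml$mult, 1)  # recipient flank: exactly once
  donor_nml <- segs[segs$chrom == "chr14" & segs$start == 1, ]
  expect_equal(donor_nml$mult, 0)  # donor flanks stay on the intact pair
})

test_that("an empty graph reconstructs the reference chromosome", {
  genome <- genome_ref(lengths = c(chr1 = 50000))
  g <- build_graph(NULL, list(), genome, recipient = "chr1")
  rec <- reconstruct(g)
  expect_equal(rec$status, "ok")
  m <- rec$models[[1]]
  expect_equal(nrow(m$walk), 1)
  expect_equal(count_junctions(m), 0)
  expect_equal(m$walk$start, 1)
  expect_equal(unname(m$walk$end), 50000)
})

test_that("basic insertion fixtures reconstruct with two junctions, inverted where reported", {
  for (id in c("Cplex4", "Cplex9", "Cplex12")) {
    r <- cached(paste0("run_", id), run_case(id))
    expect_equal(r$n_junctions_total, 2)
    expect_equal(r$n_hypothetical, 0)
    donor_rows <- r$model$walk[r$model$walk$chrom != r$fixture$recipient, ]
    expect_equal(nrow(donor_rows), 1)
    inverted <- donor_rows$strand == "-"
    expect_equal(unname(inverted), r$fixture$expected$inserted_inverted)
  }
})

test_that("the embedded-triplication fixture needs exactly one hypothetical junction", {
  r <- cached("run_Cplex6", run_case("Cplex6"))
  expect_equal(r$n_junctions_total, 3)
  expect_equal(r$n_junctions_sequenced, 2)
  expect_equal(r$n_hypothetical, 1)
  hyp <- Filter(function(j) j$support == "hypothetical",
                r$model$junctions_used)[[1]]
  exp_h <- r$fixture$expected$hypothetical_junction
  want <- junction("H", breakend(exp_h$a$chrom, exp_h$a$pos, exp_h$a$side),
                   breakend(exp_h$b$chrom, exp_h$b$pos, exp_h$b$side),
                   support = "hypothetical")
  expect_true(same_junction(hyp, want, compare_feature = FALSE))
})

test_that("the three-chromosome fixture reconstructs through six junctions", {
  r <- cached("run_Cplex11", run_case("Cplex11"))
  expect_equal(r$n_junctions_total, 6)
  expect_equal(r$n_junctions_sequenced, 5)
  expect_equal(r$n_hypothetical, 1)
  expect_equal(count_junctions(r$model), 6)
  expect_equal(count_junctions(r$model, "sequenced"), 5)
  hyp <- Filter(function(j) j$support == "hypothetical",
                r$model$junctions_used)[[1]]
  exp_h <- r$fixture$expected$hypothetical_junction
  want <- junction("H", breakend(exp_h$a$chrom, exp_h$a$pos, exp_h$a$side),
                   breakend(exp_h$b$chrom, exp_h$b$pos, exp_h$b$side),
                   support = "hypothetical")
  expect_true(same_junction(hyp, want, compare_feature = FALSE))
})

test_that("reconstruction recovers simulated truth walks with no hypothetical junctions", {
  for (seed in 1:8) {
    case <- rep_case(seed)
    truth <- case$truth
    g <- build_graph(truth$truth_cnv, truth$junctions, truth$genome,
                     recipient = truth$derivatives[[1]]$recipient)
    rec <- reconstruct(g)
    expect_equal(rec$status, "ok")
    expect_true(recovers_truth_walk(rec, truth),
                label = sprintf("seed %d truth walk recovered", seed))
  }
})

test_that("withholding one junction re-derives it as the sole hypothetical junction", {
  for (seed in 1:6) {
    case <- rep_case(seed)
    truth <- case$truth
    wi <- 1 + (seed %% length(truth$junctions))
    g <- build_graph(truth$truth_cnv, truth$junctions[-wi], truth$genome,
                     recipient = truth$derivatives[[1]]$recipient)
    rec <- reconstruct(g)
    expect_equal(rec$status, "ok")
    found <- FALSE
    for (m in rec$models) {
      hyps <- Filter(function(j) j$support == "hypothetical", m$junctions_used)
      if (length(hyps) == 1 &&
          same_junction(hyps[[1]], truth$junctions[[wi]],
                        compare_feature = FALSE)) {
        found <- TRUE
      }
    }
    expect_true(found, label = sprintf("seed %d withheld junction re-derived", seed))
  }
})

test_that("derivative sequences round-trip and hypothetical joints leave a gap", {
  case <- rep_case(5)
  truth <- case$truth
  m <- truth_derivative_model(truth)
  expect_identical(emit_derivative_sequence(m, truth$genome),
                   truth$derivatives[[1]]$seq)
  # a reference-only walk reproduces the chromosome
  genome <- tiny_genome()
  ref_model <- structure(list(
    walk = data.frame(chrom = "chr1", start = 1,
                      end = genome$lengths[["chr1"]], strand = "+"),
    junctions_used = list(), recipient = "chr1", n_hypothetical = 0),
    class = "DerivativeModel")
  expect_identical(emit_derivative_sequence(ref_model, genome),
                   genome$sequences[["chr1"]])
  # hypothetical junctions contribute an explicit N placeholder
  r6 <- cached("run_Cplex6", run_case("Cplex6"))
  g6 <- make_toy_genome(2, c(250000, 100000), 0.41, seed = 1,
                        chrom_names = c("chrX", "chr5"))
  s <- emit_derivative_sequence(r6$model, g6)
  expect_match(s, "NNNNNNNNNN")
})

test_that("copy number recomputed from any returned walk matches the input calls", {
  for (seed in c(2, 4, 7)) {
    case <- rep_case(seed)
    truth <- case$truth
    g <- build_graph(truth$truth_cnv, truth$junctions, truth$genome,
                     recipient = truth$derivatives[[1]]$recipient)
    rec <- reconstruct(g)
    for (m in rec$models) {
      cn <- walk_cnv(list(m$walk), truth$genome, recipients = m$recipient)
      expect_equal(cnv_calls(cn), cnv_calls(truth$truth_cnv))
    }
  }
})
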