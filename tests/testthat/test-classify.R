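test_that("fixture features aggregate the published evidence", {
  r4 <- cached("run_Cplex4", run_case("Cplex4"))
  f <- r4$features
  expect_equal(f$n_gains, 1)
  expect_equal(f$max_mh, 1)
  expect_equal(f$n_templated_insertions, 0)
  expect_true(f$deletion_at_insertion_site)
  expect_false(f$has_trp)
  expect_equal(f$de_novo, "no")

  r11 <- cached("run_Cplex11", run_case("Cplex11"))
  f11 <- r11$features
  expect_true(f11$has_trp)
  expect_equal(f11$n_chromosomes, 3)  # templated insert from a third chromosome
  expect_gte(f11$n_templated_insertions, 1)
  expect_true(f11$has_dup_trp_inv_dup)

  empty <- extract_features(NULL, cnv_calls(data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    cn = integer(0), baseline = integer(0))), list())
  expect_equal(empty$n_gains, 0)
  expect_equal(empty$max_mh, 0)
  expect_equal(empty$n_junctions, 0)
  expect_true(empty$net_balanced)
})

test_that("the cascade labels the six sequenced cases three chromoanasynthesis, three basic", {
  labels <- vapply(c("Cplex4", "Cplex5", "Cplex6", "Cplex9", "Cplex11", "Cplex12"),
                   function(id) {
                     cached(paste0("run_", id), run_case(id))$mechanism$label
                   }, character(1))
  expect_equal(sum(labels == "chromoanasynthesis"), 3)
  expect_equal(sum(labels == "basic_complex_insertion"), 3)
  expect_equal(unname(labels[c("Cplex5", "Cplex6", "Cplex11")]),
               rep("chromoanasynthesis", 3))
  expect_equal(unname(labels[c("Cplex4", "Cplex9", "Cplex12")]),
               rep("basic_complex_insertion", 3))
})

test_that("the balanced exchange family is called end joining despite long microhomology", {
  r <- cached("run_Family3", run_case("Family3"))
  expect_equal(r$mechanism$label, "balanced_end_joining_exchange")
  expect_equal(r$features$max_mh, 6)  # MMEJ-compatible, no gain to explain
  expect_equal(r$mechanism$proposed_repair, "MMEJ")
})

test_that("adding triplications or microhomology never demotes chromoanasynthesis to basic", {
  base <- list(n_gains = 2L, has_trp = FALSE, has_dup_trp_inv_dup = FALSE,
               max_mh = 6L, n_templated_insertions = 0L, max_templated_len = 0L,
               n_chromosomes = 2L, n_junctions = 4L, net_balanced = FALSE,
               deletion_at_insertion_site = TRUE, de_novo = "unknown")
  f0 <- structure(base, class = "CaseFeatures")
  expect_equal(classify_mechanism(f0)$label, "chromoanasynthesis")
  for (mh in c(7L, 10L, 25L)) {
    f <- f0
    f$max_mh <- mh
    expect_equal(classify_mechanism(f)$label, "chromoanasynthesis")
  }
  f <- f0
  f$has_trp <- TRUE
  expect_equal(classify_mechanism(f)$label, "chromoanasynthesis")
  # a basic case never becomes basic once a triplication appears
  fb <- f0
  fb$n_gains <- 1L
  fb$max_mh <- 2L
  expect_equal(classify_mechanism(fb)$label, "basic_complex_insertion")
  fb$has_trp <- TRUE
  expect_false(classify_mechanism(fb)$label == "basic_complex_insertion")
})

test_that("every consulted rule appears in the evidence trail with its value", {
  r <- cached("run_Cplex4", run_case("Cplex4"))
  ev <- r$mechanism$evidence
  expect_true(any(grepl("multiple copy-number gains", ev$criterion)))
  expect_true(any(grepl("replicative junction signature", ev$criterion)))
  expect_true(any(grepl("single duplication into a deletion", ev$criterion)))
  expect_true(any(grepl("de novo", ev$criterion)))
  expect_true(all(nzchar(ev$value)))
  # de novo is metadata only: flipping it never changes the label
  f <- r$features
  f$de_novo <- "yes"
  expect_equal(classify_mechanism(f)$label, r$mechanism$label)
})

test_that("classifier thresholds outside sane ranges are rejected", {
  r <- cached("run_Cplex4", run_case("Cplex4"))
  expect_error(classify_mechanism(r$features, list(mh_cutoff = -1)))
  expect_error(classify_mechanism(r$features, list(mh_cutoff = 99)))
})

test_that("classifier labels agree with the generative model on noise-free truth", {
  lab <- function(truth) {
    classify_mechanism(extract_features(NULL, cnv_calls(truth$truth_cnv),
                                        truth$junctions))$label
  }
  for (seed in 1:4) {
    basic <- rep_case(seed, n_events = 2,
                      feature_kinds = c("blunt", "microhomology",
                                        "untemplated_insertion"),
                      mh_range = c(1, 3), untemplated_range = c(1, 3))
    expect_equal(lab(basic$truth), "basic_complex_insertion")
    chromo <- rep_case(seed + 400, n_events = 3,
                       feature_kinds = c("templated_insertion", "microhomology"),
                       mh_range = c(5, 20))
    expect_equal(lab(chromo$truth), "chromoanasynthesis")
    ej <- cached(paste0("ej_cls_", seed),
                 draw_end_joining_case(seed + 800, reciprocal = seed %% 2 == 0))
    expect_equal(lab(ej$truth), "balanced_end_joining_exchange")
  }
})

test_that("repeat annotation is a pure interval lookup", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t999\t1300\tL2a", "chr2\t49\t200\tAluY"), bed)
  js <- list(junction("J1", breakend("chr1", 1100, "retains_left"),
                      breakend("chr2", 5000, "retains_right"),
                      feature = junction_feature("blunt")))
  ann <- annotate_repeats(js, bed)
  expect_equal(ann$repeat_name[ann$end == "a"], "L2a")
  expect_equal(ann$repeat_name[ann$end == "b"], "-")
  # empty annotation: everything is "-"
  empty <- GenomicRanges::GRanges()
  ann2 <- annotate_repeats(js, empty)
  expect_true(all(ann2$repeat_name == "-"))
})
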