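plp1_parent <- function() {
  fx <- cached("fx_plp1", load_case_fixture("PLP1"))
  parental_genotype(fx$parent$derivatives, "interchromosomal")
}

test_that("interchromosomal segregation enumerates all four outcomes with the reported child profiles", {
  fx <- cached("fx_plp1", load_case_fixture("PLP1"))
  outcomes <- enumerate_segregation(plp1_parent(), fx$genome,
                                    child_baseline = c(chrX = 1, chr19 = 2))
  expect_length(outcomes, 4)
  key <- vapply(outcomes, function(o) {
    paste(o$transmitted[c("chrX", "chr19")], collapse = "/")
  }, character(1))
  # derivative X + intact 19: the gene-region deletion (affected son)
  o_del <- outcomes[[which(key == "derivative/intact")]]
  expect_equal(o_del$predicted_child_cnv$type, "DEL")
  expect_equal(o_del$predicted_child_cnv$start, 60001)
  expect_equal(o_del$predicted_child_cnv$end, 100000)
  expect_equal(o_del$predicted_child_cnv$cn, 0)
  # intact X + derivative 19: the insertional duplication (carrier son)
  o_dup <- outcomes[[which(key == "intact/derivative")]]
  expect_true(any(o_dup$predicted_child_cnv$type == "DUP" &
                    o_dup$predicted_child_cnv$chrom == "chrX"))
  # both intact: no CNVs
  o_ref <- outcomes[[which(key == "intact/intact")]]
  expect_equal(nrow(o_ref$predicted_child_cnv), 0)
})

test_that("a parent without derivatives transmits a single CNV-free outcome", {
  genome <- genome_ref(lengths = c(chr1 = 50000))
  p <- parental_genotype(list(), "interchromosomal")
  outcomes <- enumerate_segregation(p, genome)
  expect_length(outcomes, 1)
  expect_equal(nrow(outcomes[[1]]$predicted_child_cnv), 0)
})

test_that("the balanced-exchange carrier transmits the deleted chromosome with its insertion", {
  fx <- cached("fx_fam3", load_case_fixture("Family3"))
  parent <- parental_genotype(fx$parent$derivatives, "interchromosomal")
  outcomes <- enumerate_segregation(parent, fx$genome)
  key <- vapply(outcomes, function(o) {
    paste(o$transmitted[c("chr7", "chr9")], collapse = "/")
  }, character(1))
  o <- outcomes[[which(key == "derivative/intact")]]
  del <- o$predicted_child_cnv[o$predicted_child_cnv$type == "DEL", ]
  expect_equal(del$chrom, "chr7")
  expect_equal(c(del$start, del$end), c(200001, 245880))
  # the 815 bp fragment rides along on the derivative chr7
  dup <- o$predicted_child_cnv[o$predicted_child_cnv$type == "DUP", ]
  expect_equal(dup$chrom, "chr9")
  expect_equal(unname(dup$end - dup$start + 1), 815)
})

test_that("single crossovers yield reciprocal duplication- and deletion-bearing products", {
  fx <- cached("fx_fam12", load_case_fixture("Family12"))
  parent <- parental_genotype(fx$parent$derivatives, "intrachromosomal")
  outcomes <- enumerate_crossovers(parent, fx$genome)
  expect_gte(length(outcomes), 2)
  expect_equal(length(outcomes) %% 2, 0)
  a <- outcomes[[1]]
  b <- outcomes[[2]]
  expect_equal(a$crossover_pos, b$crossover_pos)
  # duplication product: TRP embedded in the DUP near the proximal side
  expect_equal(a$predicted_child_cnv$type, c("DUP", "TRP", "DUP"))
  expect_equal(pattern_string(a$predicted_child_cnv, "chr19"), "DUP-TRP-DUP")
  # deletion product: slightly smaller than the duplication
  expect_equal(b$predicted_child_cnv$type, "DEL")
  dup_span <- max(a$predicted_child_cnv$end) - min(a$predicted_child_cnv$start) + 1
  expect_lt(b$predicted_child_cnv$size_bp, dup_span)
})

test_that("crossover products are exactly reciprocal against the parental imbalance", {
  fx <- cached("fx_fam12", load_case_fixture("Family12"))
  parent <- parental_genotype(fx$parent$derivatives, "intrachromosomal")
  genome <- fx$genome
  outcomes <- enumerate_crossovers(parent, genome)
  # segment-count arithmetic: summed child deviations from baseline over
  # the two reciprocal products equal the parental deviation
  deviation <- function(segs, chrom) {
    pos <- seq(1, genome$lengths[[chrom]], by = 500)
    vapply(pos, function(p) {
      row <- segs[segs$chrom == chrom & segs$start <= p & segs$end >= p, ]
      row$cn[1] - row$baseline[1]
    }, numeric(1))
  }
  parental <- walk_cnv(lapply(parent$derivatives, `[[`, "walk"), genome,
                       recipients = "chr19")
  dev_parent <- deviation(parental, "chr19")
  for (i in seq(1, min(6, length(outcomes)), by = 2)) {
    dev_a <- deviation(outcomes[[i]]$child_segments, "chr19")
    dev_b <- deviation(outcomes[[i + 1]]$child_segments, "chr19")
    expect_equal(dev_a + dev_b, dev_parent)
  }
})

test_that("transmission is Mendelian: one whole parental homolog per chromosome", {
  fx <- cached("fx_plp1", load_case_fixture("PLP1"))
  outcomes <- enumerate_segregation(plp1_parent(), fx$genome)
  for (o in outcomes) {
    expect_setequal(names(o$transmitted), c("chrX", "chr19"))
    expect_true(all(o$transmitted %in% c("derivative", "intact")))
  }
})

test_that("crossovers inside rearranged material are excluded with a flag", {
  fx <- cached("fx_fam12", load_case_fixture("Family12"))
  parent <- parental_genotype(fx$parent$derivatives, "intrachromosomal")
  # force the grid into the rearranged q-arm interval: every position is
  # covered twice (or sits in duplicated material) and must be excluded
  outcomes <- enumerate_crossovers(parent, fx$genome, interval_grid_bp = 300,
                                   region = c(200001, 201440))
  expect_length(outcomes, 0)
  expect_gt(length(attr(outcomes, "excluded")), 0)
})

test_that("children are matched to outcomes and unrelated CNVs appear as residual", {
  r <- cached("run_Family12", run_case("Family12"))
  for (ch in r$children) {
    expect_equal(nrow(ch$match$residual), 0)
    expect_equal(nrow(ch$match$unpredicted), 0)
  }
  # an unrelated CNV is reported as residual
  fx <- cached("fx_fam12", load_case_fixture("Family12"))
  parent <- parental_genotype(fx$parent$derivatives, "intrachromosomal")
  outcomes <- enumerate_crossovers(parent, fx$genome)
  calls <- rbind(fx$children[[1]]$calls,
                 cnv_calls(data.frame(chrom = "chr19", start = 280001,
                                      end = 290000, cn = 1, baseline = 2)))
  m <- match_child(calls, outcomes)
  expect_equal(nrow(m$residual), 1)
  expect_equal(m$residual$start, 280001)
})

test_that("family reports match every child with zero residual", {
  for (id in c("PLP1", "Family3")) {
    r <- cached(paste0("run_", id), run_case(id))
    for (ch in r$children) {
      expect_equal(nrow(ch$match$residual), 0,
                   label = sprintf("%s child %s residual", id, ch$id))
    }
  }
})
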