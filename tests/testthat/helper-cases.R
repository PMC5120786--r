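# Shared fixtures for the suite: a small deterministic genome, a basic
# two-switch insertion chain, and a cache so expensive seeded draws are
# generated once per test run.

.insmech_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .insmech_cache)) {
    assign(key, force(expr), envir = .insmech_cache)
  }
  get(key, envir = .insmech_cache)
}

tiny_genome <- function() {
  cached("tiny_genome", make_toy_genome(2, c(60000, 50000), 0.41, seed = 11))
}

# donor fragment of chr2 copied into a deleted interval of chr1
basic_chain <- function(mh1 = 3L, mh2 = 0L) {
  event_chain(
    start = list(chrom = "chr1", pos = 20000),
    events = list(
      switch_event("chr2", 10000, "direct", mh_len = mh1, seg_len = 800),
      switch_event("chr1", 21500, "direct", mh_len = mh2)
    ),
    resolution = list(chrom = "chr1", pos = 21500),
    seed = 1
  )
}

basic_truth <- function() {
  cached("basic_truth", simulate_replicative(tiny_genome(), basic_chain()))
}

rep_case <- function(seed, ...) {
  args <- list(...)
  key <- paste0("rep_", seed, "_", paste(names(args), unlist(args), collapse = "_"))
  cached(key, do.call(draw_replicative_case, c(list(seed = seed), args)))
}

# brute-force microhomology oracle: scan all overlap lengths k, comparing
# the two reference flanks read in derivative orientation
oracle_mh <- function(a, b, genome, kmax = 60) {
  flank_a <- function(k) {
    if (a$side == "retains_left") genome_seq(genome, a$chrom, a$pos - k + 1, a$pos)
    else genome_seq(genome, a$chrom, a$pos, a$pos + k - 1, "-")
  }
  flank_b <- function(k) {
    if (b$side == "retains_right") genome_seq(genome, b$chrom, b$pos, b$pos + k - 1)
    else genome_seq(genome, b$chrom, b$pos - k + 1, b$pos, "-")
  }
  best <- 0L
  for (k in seq_len(kmax)) {
    ok <- tryCatch(flank_a(k) == flank_b(k), error = function(e) NA)
    if (is.na(ok)) break
    if (ok) best <- k
  }
  best
}

# does any reported model reproduce the simulated derivative sequence
# (directly or as its reverse complement)?
recovers_truth_walk <- function(recon, truth) {
  target <- truth$derivatives[[1]]$seq
  for (m in recon$models) {
    if (m$n_hypothetical > 0) next
    s <- emit_derivative_sequence(m, truth$genome)
    if (s == target || s == revcomp(target)) return(TRUE)
  }
  FALSE
}

expect_same_junction <- function(x, y) {
  expect_true(same_junction(x, y),
              label = sprintf("%s matches %s", format(x), format(y)))
}
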