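# Seeded random rearrangement cases for property testing and calibration.
#
# The generator owns the study conditions: toy genomes of a few tens of kb,
# template-switch chains of 1-4 events, junctional microhomology of 0-20 bp,
# untemplated inserts of 1-20 bp, and templated inserts copied from 1-3 loci
# on up to three chromosomes. Loci are kept mutually disjoint (>= 60 bp
# buffers) so the microhomology-engineering step of the simulator cannot
# corrupt a neighbouring joint.

# TRUE when no `min_len`-mer of `ins` occurs anywhere in the genome (either
# strand): the insert is genuinely untemplated at that detection threshold.
insert_is_untemplated <- function(genome, ins, min_len = 10L) {
  if (nchar(ins) < min_len) return(TRUE)
  subjects <- Biostrings::DNAStringSet(genome$sequences)
  for (i in seq_len(nchar(ins) - min_len + 1L)) {
    kmer <- substr(ins, i, i + min_len - 1L)
    for (pat in c(kmer, revcomp(kmer))) {
      if (sum(Biostrings::vcountPattern(pat, subjects)) > 0) return(FALSE)
    }
  }
  TRUE
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Draw a seeded random replicative rearrangement case
#'
#' Generates a toy genome (unless one is supplied), a random
#' template-switch chain with the requested number of events and feature
#' spectrum, and the simulated truth model. All loci used by the chain are
#' pairwise disjoint, and untemplated inserts are verified (and redrawn if
#' necessary) to contain no `min_template_len`-mer present in the genome,
#' so every truth label is recoverable by annotation.
#'
#' @param seed Integer seed; the only source of randomness.
#' @param genome Optional [genome_ref()]; default three chromosomes of
#'   60/50/40 kb.
#' @param n_events Number of switches (junctions); default drawn from 2-4.
#' @param feature_kinds Feature spectrum to draw joints from.
#' @param mh_range,untemplated_range,part_len_range,seg_len_range,del_range
#'   Inclusive ranges for microhomology length, untemplated-insert length,
#'   templated-part length, copied-segment length, and the deletion at the
#'   insertion site.
#' @param n_parts_range Range of templated-insert part counts.
#' @param min_template_len Detection threshold used for the
#'   untemplated-insert genome check.
#' @param max_tries Redraw budget for a fully clean case.
#' @return `list(genome, chain, truth)` where `genome` is the engineered
#'   genome the truth model lives on.
#' @export
draw_replicative_case <- function(seed, genome = NULL, n_events = NULL,
                                  feature_kinds = c("blunt", "microhomology",
                                                    "untemplated_insertion",
                                                    "templated_insertion"),
                                  mh_range = c(1, 20),
                                  untemplated_range = c(1, 20),
                                  part_len_range = c(25, 400),
                                  n_parts_range = c(1, 3),
                                  seg_len_range = c(300, 1500),
                                  del_range = c(300, 2000),
                                  min_template_len = 10L,
                                  max_tries = 25L) {
  for (try in seq_len(max_tries)) {
    res <- with_seed(seed * 1000L + try, {
      g <- genome
      if (is.null(g)) {
        g <- make_toy_genome(3, c(60000, 50000, 40000), 0.41,
                             seed = sample.int(1e6, 1))
      }
      draw_one_replicative(g, n_events, feature_kinds, mh_range,
                           untemplated_range, part_len_range, n_parts_range,
                           seg_len_range, del_range, min_template_len,
                           seed = seed)
    })
    if (!is.null(res)) return(res)
  }
  stop("could not draw a clean replicative case for seed ", seed)
}

draw_one_replicative <- function(g, n_events, feature_kinds, mh_range,
                                 untemplated_range, part_len_range,
                                 n_parts_range, seg_len_range, del_range,
                                 min_template_len, seed) {
  margin <- 3000L
  buffer <- 60L
  reserved <- list()
  reserve <- function(chrom, start, end) {
    for (r in reserved) {
      if (r$chrom == chrom && start <= r$end + buffer && end >= r$start - buffer) {
        return(FALSE)
      }
    }
    reserved[[length(reserved) + 1]] <<- list(chrom = chrom, start = start, end = end)
    TRUE
  }
  draw_locus <- function(len) {
    for (i in 1:200) {
      chrom <- sample(names(g$lengths), 1)
      L <- g$lengths[[chrom]]
      if (L - len - 2 * margin < 1) next
      start <- sample.int(L - len - 2 * margin, 1) + margin
      if (reserve(chrom, start, start + len - 1L)) {
        return(list(chrom = chrom, start = start, end = start + len - 1L))
      }
    }
    NULL
  }

  if (is.null(n_events)) n_events <- sample(2:4, 1)
  rec <- names(g$lengths)[1]
  L1 <- g$lengths[[rec]]
  del <- sample(del_range[1]:del_range[2], 1)
  s <- sample.int(L1 - del - 2 * margin, 1) + margin
  r <- s + del + 1L
  if (!reserve(rec, s - buffer, r + buffer)) return(NULL)

  events <- vector("list", n_events)
  for (k in seq_len(n_events)) {
    kind <- sample(feature_kinds, 1)
    mh <- 0L
    untemp <- ""
    tparts <- NULL
    if (kind == "microhomology") {
      mh <- sample(mh_range[1]:mh_range[2], 1)
    } else if (kind == "untemplated_insertion") {
      len <- sample(untemplated_range[1]:untemplated_range[2], 1)
      ok <- FALSE
      for (i in 1:60) {
        untemp <- random_dna(len)
        if (insert_is_untemplated(g, untemp, min_template_len)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) untemp <- random_dna(min(len, min_template_len - 1L))
    } else if (kind == "templated_insertion") {
      np <- sample(n_parts_range[1]:n_parts_range[2], 1)
      tparts <- do.call(rbind, lapply(seq_len(np), function(i) {
        len <- sample(part_len_range[1]:part_len_range[2], 1)
        loc <- draw_locus(len)
        if (is.null(loc)) return(NULL)
        data.frame(chrom = loc$chrom, start = loc$start, end = loc$end,
                   strand = sample(c("+", "-"), 1))
      }))
      if (is.null(tparts) || nrow(tparts) < np) return(NULL)
    }
    if (k < n_events) {
      seg_len <- sample(seg_len_range[1]:seg_len_range[2], 1)
      loc <- draw_locus(seg_len)
      if (is.null(loc)) return(NULL)
      orientation <- sample(c("direct", "inverted"), 1)
      target_pos <- if (orientation == "direct") loc$start else loc$end
      events[[k]] <- switch_event(loc$chrom, target_pos, orientation,
                                  mh_len = mh, untemplated_insert = untemp,
                                  templated_insert_sources = tparts,
                                  seg_len = seg_len)
    } else {
      events[[k]] <- switch_event(rec, r, "direct", mh_len = mh,
                                  untemplated_insert = untemp,
                                  templated_insert_sources = tparts)
    }
  }
  chain <- event_chain(list(chrom = rec, pos = s), events,
                       list(chrom = rec, pos = r), seed = seed)
  truth <- tryCatch(simulate_replicative(g, chain, engineer = TRUE),
                    error = function(e) NULL)
  if (is.null(truth)) return(NULL)
  # the engineering pass may have rewritten reference bases: re-verify that
  # every untemplated insert is still sourceless on the final genome
  for (j in truth$junctions) {
    f <- j$feature
    if (f$kind == "untemplated_insertion" &&
        !insert_is_untemplated(truth$genome, f$insert_seq, min_template_len)) {
      return(NULL)
    }
  }
  list(genome = truth$genome, chain = chain, truth = truth)
}

#' Draw a seeded random end-joining insertional exchange
#'
#' @param seed Integer seed.
#' @param genome Optional [genome_ref()].
#' @param reciprocal Also move a fragment in the opposite direction.
#' @param trim_bp Donor bases lost during the exchange (left flank).
#' @return `list(genome, truth)`.
#' @export
draw_end_joining_case <- function(seed, genome = NULL, reciprocal = FALSE,
                                  trim_bp = 0L) {
  with_seed(seed * 1000L + 1L, {
    g <- genome
    if (is.null(g)) {
      g <- make_toy_genome(2, c(60000, 50000), 0.41, seed = sample.int(1e6, 1))
    }
    margin <- 3000L
    frag_len <- sample(2000:8000, 1) + trim_bp
    d_start <- sample.int(g$lengths[[1]] - frag_len - 2 * margin, 1) + margin
    donor <- list(chrom = names(g$lengths)[1], start = d_start,
                  end = d_start + frag_len - 1L)
    acc_pos <- sample.int(g$lengths[[2]] - 2 * margin, 1) + margin
    acceptor <- list(chrom = names(g$lengths)[2], pos = acc_pos)
    recip <- NULL
    if (reciprocal) {
      rlen <- sample(300:1500, 1)
      recip <- list(chrom = names(g$lengths)[2], start = acc_pos + 1L,
                    end = acc_pos + rlen)
    }
    truth <- simulate_end_joining_insertion(g, donor, acceptor,
                                            reciprocal_fragment = recip,
                                            seed = sample.int(1e6, 1),
                                            trim_left = trim_bp)
    list(genome = truth$genome, truth = truth)
  })
}
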