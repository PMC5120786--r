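# Meiotic transmission of parental insertions. Interchromosomal insertions
# segregate independently: each involved chromosome transmits either the
# derivative or the intact homolog, giving 2^k outcomes. Intrachromosomal
# insertions additionally recombine: a single crossover between the donor
# and acceptor loci yields two reciprocal recombinant products, one
# duplication-bearing and one deletion-bearing. The other parent is assumed
# to contribute reference chromosomes (configurable baseline for sex
# chromosomes).

#' Parental genotype for transmission modelling
#'
#' @param derivatives List of derivative descriptions, each a
#'   `DerivativeModel` or a `list(recipient =, walk =)` with a walk
#'   data.frame (`chrom`, `start`, `end`, `strand`). At most one
#'   derivative per chromosome; the other homolog of each involved
#'   chromosome is implied intact.
#' @param insertion_type `"interchromosomal"` or `"intrachromosomal"`.
#' @return An object of class `ParentalGenotype`.
#' @export
parental_genotype <- function(derivatives,
                              insertion_type = c("interchromosomal",
                                                 "intrachromosomal")) {
  insertion_type <- match.arg(insertion_type)
  recs <- vapply(derivatives, `[[`, character(1), "recipient")
  abort_if(anyDuplicated(recs) > 0, "at most one derivative per chromosome")
  structure(list(derivatives = derivatives, insertion_type = insertion_type),
            class = "ParentalGenotype")
}

# child copy number from the transmitted homologs: the other parent
# contributes child_baseline - 1 reference copies of every chromosome
child_cn <- function(walks, genome, child_baseline) {
  out <- list()
  for (chrom in names(genome$lengths)) {
    L <- genome$lengths[[chrom]]
    segs <- do.call(rbind, lapply(walks, function(w) {
      w[w$chrom == chrom, , drop = FALSE]
    }))
    cuts <- sort(unique(c(0L, L,
                          if (!is.null(segs) && nrow(segs)) c(segs$start - 1L, segs$end))))
    cuts <- cuts[cuts >= 0 & cuts <= L]
    starts <- cuts[-length(cuts)] + 1L
    ends <- cuts[-1]
    uses <- vapply(seq_along(starts), function(i) {
      if (is.null(segs) || nrow(segs) == 0) return(0L)
      sum(segs$start <= starts[i] & segs$end >= ends[i])
    }, integer(1))
    base <- child_baseline[[chrom]]
    cn <- uses + base - 1L
    keep <- c(TRUE, cn[-1] != cn[-length(cn)])
    idx <- cumsum(keep)
    out[[chrom]] <- data.frame(chrom = chrom,
                               start = as.integer(tapply(starts, idx, min)),
                               end = as.integer(tapply(ends, idx, max)),
                               cn = cn[keep], baseline = base,
                               row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

intact_walk <- function(genome, chrom) {
  data.frame(chrom = chrom, start = 1L, end = genome$lengths[[chrom]],
             strand = "+")
}

transmission_outcome <- function(transmitted, walks, genome, child_baseline,
                                 crossover_pos = NA_integer_) {
  segs <- child_cn(walks, genome, child_baseline)
  structure(list(transmitted = transmitted,
                 crossover_pos = crossover_pos,
                 predicted_child_cnv = cnv_calls(segs),
                 child_segments = segs,
                 walks = walks),
            class = "TransmissionOutcome")
}

#' @export
print.TransmissionOutcome <- function(x, ...) {
  tr <- paste(sprintf("%s=%s", names(x$transmitted), x$transmitted),
              collapse = ", ")
  cat(sprintf("TransmissionOutcome: %s%s\n", tr,
              if (!is.na(x$crossover_pos)) {
                sprintf(" (crossover at %d)", x$crossover_pos)
              } else ""))
  if (nrow(x$predicted_child_cnv) == 0) {
    cat("  no predicted child CNVs\n")
  } else {
    print(x$predicted_child_cnv, row.names = FALSE)
  }
  invisible(x)
}

#' Enumerate segregation outcomes of an interchromosomal insertion
#'
#' All `2^k` combinations of derivative-versus-intact transmission over
#' the `k` involved chromosomes, each with the predicted child
#' copy-number calls (the other parent contributing reference
#' chromosomes).
#'
#' @param parent A [parental_genotype()] with
#'   `insertion_type = "interchromosomal"`.
#' @param genome A [genome_ref()] (sequence optional).
#' @param child_baseline Named integer vector of the child's expected
#'   baseline copy number per chromosome (e.g. `1` for the X of a male
#'   child); defaults to the genome ploidy.
#' @return List of `TransmissionOutcome`s.
#' @export
enumerate_segregation <- function(parent, genome, child_baseline = NULL) {
  abort_if(parent$insertion_type != "interchromosomal",
           "enumerate_segregation models interchromosomal insertions; use enumerate_crossovers")
  if (is.null(child_baseline)) child_baseline <- genome$ploidy
  ders <- parent$derivatives
  k <- length(ders)
  involved <- vapply(ders, `[[`, character(1), "recipient")
  others <- setdiff(names(genome$lengths), involved)
  outcomes <- list()
  picks <- if (k == 0) list(logical(0)) else
    lapply(seq_len(2 ^ k) - 1L, function(m) as.logical(bitwAnd(m, 2 ^ (seq_len(k) - 1)) > 0))
  for (pick in picks) {
    transmitted <- stats::setNames(ifelse(pick, "derivative", "intact"), involved)
    walks <- lapply(others, intact_walk, genome = genome)
    for (i in seq_len(k)) {
      walks[[length(walks) + 1]] <- if (pick[i]) ders[[i]]$walk
                                    else intact_walk(genome, involved[i])
    }
    outcomes[[length(outcomes) + 1]] <-
      transmission_outcome(transmitted, walks, genome, child_baseline)
  }
  outcomes
}

# reference-collinearity: positions covered by exactly one walk row, on the
# derivative's own chromosome, traversed in + orientation
crossover_eligible <- function(walk, chrom, x) {
  covering <- which(walk$chrom == chrom & walk$start <= x & walk$end >= x)
  length(covering) == 1 && walk$strand[covering] == "+"
}

#' Enumerate single-crossover outcomes of an intrachromosomal insertion
#'
#' For each grid-sampled crossover position in the unrearranged interval
#' between the donor and acceptor loci, homologous recombination between
#' the derivative and the intact homolog yields the two reciprocal
#' recombinant products; each is returned with its predicted child
#' copy-number calls. Grid positions falling inside rearranged material
#' (covered more than once, or traversed inverted) would produce further
#' complexity and are excluded with a flag.
#'
#' @param parent A [parental_genotype()] with
#'   `insertion_type = "intrachromosomal"` and a single derivative.
#' @param genome A [genome_ref()] (sequence optional).
#' @param interval_grid_bp Crossover grid spacing (default 10 kb).
#' @param child_baseline As in [enumerate_segregation()].
#' @param region Optional `c(lo, hi)` crossover interval; by default the
#'   largest stretch between consecutive breakends on the recipient,
#'   which is the unrearranged interval separating the acceptor
#'   (insertion) site from the donor region.
#' @return List of `TransmissionOutcome`s (two per crossover position),
#'   with attribute `excluded` listing skipped grid positions.
#' @export
enumerate_crossovers <- function(parent, genome, interval_grid_bp = 10000L,
                                 child_baseline = NULL, region = NULL) {
  abort_if(parent$insertion_type != "intrachromosomal",
           "enumerate_crossovers models intrachromosomal insertions")
  abort_if(length(parent$derivatives) != 1,
           "intrachromosomal modelling expects a single derivative")
  if (is.null(child_baseline)) child_baseline <- genome$ploidy
  der <- parent$derivatives[[1]]
  chrom <- der$recipient
  walk <- der$walk
  # breakend span on the recipient: discontinuities between consecutive rows
  bps <- integer(0)
  for (i in seq_len(nrow(walk) - 1)) {
    a <- walk[i, ]
    b <- walk[i + 1, ]
    adjacent <- a$chrom == b$chrom && a$strand == "+" && b$strand == "+" &&
      b$start == a$end + 1
    if (adjacent) next
    if (a$chrom == chrom) bps <- c(bps, if (a$strand == "+") a$end else a$start)
    if (b$chrom == chrom) bps <- c(bps, if (b$strand == "+") b$start else b$end)
  }
  abort_if(length(bps) < 2, "derivative walk shows no rearranged span on %s", chrom)
  if (is.null(region)) {
    bps <- sort(unique(bps))
    gaps <- diff(bps)
    i <- which.max(gaps)
    region <- c(bps[i], bps[i + 1])
  }
  grid <- seq.int(region[1] + interval_grid_bp, region[2] - 1L,
                  by = interval_grid_bp)
  others <- setdiff(names(genome$lengths), chrom)
  outcomes <- list()
  excluded <- integer(0)
  for (x in grid) {
    if (!crossover_eligible(walk, chrom, x)) {
      excluded <- c(excluded, x)
      next
    }
    r <- which(walk$chrom == chrom & walk$start <= x & walk$end >= x)
    # product A: derivative prefix + intact suffix
    pre <- walk[seq_len(r), , drop = FALSE]
    pre$end[r] <- x
    walk_a <- rbind(pre, data.frame(chrom = chrom, start = x + 1L,
                                    end = genome$lengths[[chrom]], strand = "+"))
    # product B: intact prefix + derivative suffix
    post <- walk[r:nrow(walk), , drop = FALSE]
    post$start[1] <- x + 1L
    walk_b <- rbind(data.frame(chrom = chrom, start = 1L, end = x, strand = "+"),
                    post)
    for (w in list(walk_a, walk_b)) {
      walks <- c(lapply(others, intact_walk, genome = genome), list(w))
      outcomes[[length(outcomes) + 1]] <- transmission_outcome(
        stats::setNames("recombinant", chrom), walks, genome, child_baseline,
        crossover_pos = x)
    }
  }
  attr(outcomes, "excluded") <- excluded
  outcomes
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- min(e1, e2) - max(s1, s2) + 1
  if (ov <= 0) return(0)
  ov / max(e1 - s1 + 1, e2 - s2 + 1)
}

#' Match observed child CNVs against predicted transmission outcomes
#'
#' Scores each outcome by summed reciprocal overlap between same-type
#' predicted and observed calls, and reports the residual: observed CNVs
#' unexplained by the best outcome (the "additional complexities").
#'
#' @param child_calls Observed child `CNVCall` data.frame.
#' @param outcomes List of `TransmissionOutcome`s.
#' @param slop_bp Boundary slack treated as matching (default 1 kb).
#' @param min_recip Minimum reciprocal overlap for a call match.
#' @return `list(best, score, matched, residual, unpredicted)` where
#'   `best` is the index of the best-scoring outcome.
#' @export
match_child <- function(child_calls, outcomes, slop_bp = 1000L,
                        min_recip = 0.5) {
  score_one <- function(outcome) {
    pred <- outcome$predicted_child_cnv
    matched_obs <- rep(FALSE, nrow(child_calls))
    matched_pred <- rep(FALSE, nrow(pred))
    score <- 0
    if (nrow(pred) && nrow(child_calls)) {
      for (i in seq_len(nrow(pred))) {
        best_j <- 0
        best_ro <- 0
        for (j in seq_len(nrow(child_calls))) {
          if (matched_obs[j]) next
          if (pred$chrom[i] != child_calls$chrom[j]) next
          if (pred$type[i] != child_calls$type[j]) next
          ro <- reciprocal_overlap(pred$start[i], pred$end[i],
                                   child_calls$start[j], child_calls$end[j])
          # boundary fuzz up to slop_bp counts as a perfect match
          if (abs(pred$start[i] - child_calls$start[j]) <= slop_bp &&
              abs(pred$end[i] - child_calls$end[j]) <= slop_bp) ro <- 1
          if (ro > best_ro) {
            best_ro <- ro
            best_j <- j
          }
        }
        if (best_j > 0 && best_ro >= min_recip) {
          matched_obs[best_j] <- TRUE
          matched_pred[i] <- TRUE
          score <- score + best_ro
        }
      }
    }
    # penalize unexplained calls on either side
    score <- score - 0.25 * sum(!matched_obs) - 0.25 * sum(!matched_pred)
    list(score = score, matched_obs = matched_obs, matched_pred = matched_pred)
  }
  scored <- lapply(outcomes, score_one)
  best <- which.max(vapply(scored, `[[`, numeric(1), "score"))
  s <- scored[[best]]
  list(best = best,
       score = s$score,
       matched = child_calls[s$matched_obs, , drop = FALSE],
       residual = child_calls[!s$matched_obs, , drop = FALSE],
       unpredicted = outcomes[[best]]$predicted_child_cnv[!s$matched_pred, , drop = FALSE])
}
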