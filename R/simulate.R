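#' One template switch of a replicative repair chain
#'
#' A `SwitchEvent` describes one jump of a stalled replication fork: the
#' locus it lands on, the orientation in which it resumes copying, the
#' number of bases copied before the next switch (`seg_len`, ignored for
#' the final event, which runs to the recipient telomere), and the
#' junctional signature left at the joint. A joint shows microhomology
#' *or* inserted sequence, never both.
#'
#' @param target_chrom,target_pos Landing locus (1-based).
#' @param orientation `"direct"` (copying proceeds rightward) or
#'   `"inverted"` (the template is copied in reverse complement, the fork
#'   moving leftward from `target_pos`).
#' @param mh_len Microhomology length at the joint (0 for blunt).
#' @param untemplated_insert Nucleotide string inserted at the joint with
#'   no genomic source ("" for none).
#' @param templated_insert_sources Optional data.frame
#'   (`chrom`, `start`, `end`, `strand`) of loci whose sequence is copied,
#'   in order, into the joint.
#' @param seg_len Bases replicated on the landing template before the
#'   next switch; `NA` for the final event.
#' @return An object of class `SwitchEvent`.
#' @export
switch_event <- function(target_chrom, target_pos, orientation = "direct",
                         mh_len = 0L, untemplated_insert = "",
                         templated_insert_sources = NULL, seg_len = NA) {
  orientation <- match.arg(orientation, c("direct", "inverted"))
  has_ins <- nzchar(untemplated_insert) || !is.null(templated_insert_sources)
  abort_if(mh_len > 0 && has_ins,
           "a joint shows microhomology OR inserted sequence, not both")
  abort_if(nzchar(untemplated_insert) && !is.null(templated_insert_sources),
           "a joint carries one insert kind at a time")
  if (!is.null(templated_insert_sources)) {
    templated_insert_sources <-
      as.data.frame(templated_insert_sources)[, c("chrom", "start", "end", "strand")]
  }
  structure(list(target_chrom = target_chrom,
                 target_pos = as.integer(target_pos),
                 orientation = orientation, mh_len = as.integer(mh_len),
                 untemplated_insert = untemplated_insert,
                 templated_insert_sources = templated_insert_sources,
                 seg_len = if (is.na(seg_len)) NA_integer_ else as.integer(seg_len)),
            class = "SwitchEvent")
}

#' A chain of template switches
#'
#' Replication starts on the recipient chromosome, proceeds to
#' `start$pos`, then follows the events in order; the final event lands
#' back on the recipient at `resolution` and replication runs to the
#' telomere. An n-event chain therefore produces n breakpoint junctions.
#'
#' @param start `list(chrom =, pos =)`: last recipient base replicated
#'   before the first switch.
#' @param events List of [switch_event()]s (at least one); the last
#'   event's target must equal `resolution`.
#' @param resolution `list(chrom =, pos =)` where replication rejoins the
#'   recipient chromosome (same chromosome as `start`).
#' @param seed Integer seed recorded with the chain.
#' @return An object of class `EventChain`.
#' @export
event_chain <- function(start, events, resolution, seed = 1L) {
  abort_if(length(events) < 1, "an event chain needs at least one event")
  abort_if(start$chrom != resolution$chrom,
           "insertion-type chains start and resolve on the same chromosome")
  last <- events[[length(events)]]
  abort_if(last$target_chrom != resolution$chrom ||
             last$target_pos != resolution$pos,
           "the final event's target must equal the resolution point")
  structure(list(start = list(chrom = start$chrom, pos = as.integer(start$pos)),
                 events = events,
                 resolution = list(chrom = resolution$chrom,
                                   pos = as.integer(resolution$pos)),
                 seed = as.integer(seed)),
            class = "EventChain")
}

# ---- oriented-flank helpers (derivative space) ----------------------------

complement1 <- function(b) chartr("ACGT", "TGCA", b)

# last n derivative bases of a flank ending at dep$pos moving dep$strand
dep_tail <- function(genome, dep, n) {
  if (n == 0) return("")
  if (dep$strand == "+") genome_seq(genome, dep$chrom, dep$pos - n + 1, dep$pos)
  else genome_seq(genome, dep$chrom, dep$pos, dep$pos + n - 1, "-")
}

# first n derivative bases of a flank starting at land$pos moving land$strand
land_head <- function(genome, land, n) {
  if (n == 0) return("")
  if (land$strand == "+") genome_seq(genome, land$chrom, land$pos, land$pos + n - 1)
  else genome_seq(genome, land$chrom, land$pos - n + 1, land$pos, "-")
}

# derivative-space base that would follow the departure flank if it continued
dep_cont <- function(genome, dep) {
  if (dep$strand == "+") genome_base(genome, dep$chrom, dep$pos + 1)
  else {
    b <- genome_base(genome, dep$chrom, dep$pos - 1)
    if (is.na(b)) NA_character_ else complement1(b)
  }
}

# derivative-space base immediately upstream of the landing flank
land_upstream <- function(genome, land) {
  if (land$strand == "+") genome_base(genome, land$chrom, land$pos - 1)
  else {
    b <- genome_base(genome, land$chrom, land$pos + 1)
    if (is.na(b)) NA_character_ else complement1(b)
  }
}

# write derivative-space bases into the landing flank at `offset` bases in
land_write <- function(genome, land, offset, bases) {
  n <- nchar(bases)
  if (land$strand == "+") {
    genome_write(genome, land$chrom, land$pos + offset, bases)
  } else {
    genome_write(genome, land$chrom, land$pos - offset - n + 1, revcomp(bases))
  }
}

# set the derivative-space base upstream of the landing flank
land_upstream_write <- function(genome, land, base) {
  if (land$strand == "+") {
    if (land$pos - 1 >= 1) genome_write(genome, land$chrom, land$pos - 1, base)
    else genome
  } else {
    if (land$pos + 1 <= genome$lengths[[land$chrom]]) {
      genome_write(genome, land$chrom, land$pos + 1, complement1(base))
    } else genome
  }
}

part_seq <- function(genome, p) {
  genome_seq(genome, p$chrom, p$start, p$end, p$strand)
}

# derivative-space base following a templated-insert source in its orientation
part_cont <- function(genome, p) {
  if (p$strand == "+") genome_base(genome, p$chrom, p$end + 1)
  else {
    b <- genome_base(genome, p$chrom, p$start - 1)
    if (is.na(b)) NA_character_ else complement1(b)
  }
}

flip_part <- function(p) {
  p$strand <- if (p$strand == "+") "-" else "+"
  p
}

part_cont_write <- function(genome, p, base) {
  if (p$strand == "+") {
    if (p$end + 1 <= genome$lengths[[p$chrom]]) {
      genome_write(genome, p$chrom, p$end + 1, base)
    } else genome
  } else {
    if (p$start - 1 >= 1) genome_write(genome, p$chrom, p$start - 1, complement1(base))
    else genome
  }
}

joint_insert_seq <- function(genome, feature) {
  if (is.null(feature)) return("")
  if (feature$kind == "untemplated_insertion") return(feature$insert_seq)
  if (feature$kind == "templated_insertion") {
    return(paste(vapply(seq_len(nrow(feature$template_parts)), function(i) {
      part_seq(genome, feature$template_parts[i, ])
    }, character(1)), collapse = ""))
  }
  ""
}

# Verify that a planned joint's truth label is well defined on this genome:
# the microhomology tract (if any) is shared exactly, and neither anchor can
# extend across the joint. Returns NULL when clean, else a message.
check_joint <- function(genome, dep, land, feature) {
  m <- if (!is.null(feature) && feature$kind == "microhomology") feature$mh_len else 0L
  ins <- joint_insert_seq(genome, feature)
  if (m > 0) {
    tract_a <- dep_tail(genome, dep, m)
    tract_b <- land_head(genome, land, m)
    if (tract_a != tract_b) {
      return(sprintf("flanks do not share a %d bp tract (%s vs %s)", m, tract_a, tract_b))
    }
    x1 <- dep_cont(genome, dep)
    b1 <- land_head(genome, land, m + 1)
    if (!is.na(x1) && substr(b1, m + 1, m + 1) == x1) {
      return("microhomology tract extends beyond requested length (right)")
    }
    x2 <- land_upstream(genome, land)
    a2 <- dep_tail(genome, dep, m + 1)
    if (!is.na(x2) && substr(a2, 1, 1) == x2) {
      return("microhomology tract extends beyond requested length (left)")
    }
  } else if (nzchar(ins)) {
    x1 <- dep_cont(genome, dep)
    if (!is.na(x1) && substr(ins, 1, 1) == x1) {
      return("insert begins with the departing flank's next reference base")
    }
    x2 <- land_upstream(genome, land)
    if (!is.na(x2) && substr(ins, nchar(ins), nchar(ins)) == x2) {
      return("insert ends with the landing flank's previous reference base")
    }
  } else {
    x1 <- dep_cont(genome, dep)
    if (!is.na(x1) && land_head(genome, land, 1) == x1) {
      return("blunt joint but flanks share sequence (right)")
    }
    x2 <- land_upstream(genome, land)
    if (!is.na(x2) && dep_tail(genome, dep, 1) == x2) {
      return("blunt joint but flanks share sequence (left)")
    }
  }
  if (!is.null(feature) && feature$kind == "templated_insertion") {
    tp <- feature$template_parts
    if (nrow(tp) > 1) {
      for (i in seq_len(nrow(tp) - 1)) {
        cb <- part_cont(genome, tp[i, ])
        nxt <- substr(part_seq(genome, tp[i + 1, ]), 1, 1)
        if (!is.na(cb) && cb == nxt) {
          return(sprintf("template part %d extends into part %d in the reference", i, i + 1))
        }
        # the same guard must hold when the insert is read in reverse
        # complement, or greedy decomposition of the flipped read overshoots
        ps <- part_seq(genome, tp[i, ])
        cb2 <- part_cont(genome, flip_part(tp[i + 1, ]))
        nxt2 <- complement1(substr(ps, nchar(ps), nchar(ps)))
        if (!is.na(cb2) && cb2 == nxt2) {
          return(sprintf("template part %d extends into part %d on the flipped read", i + 1, i))
        }
      }
    }
  }
  NULL
}

# Mutate the toy genome so the joint's requested signature holds exactly.
engineer_joint <- function(genome, dep, land, feature) {
  m <- if (!is.null(feature) && feature$kind == "microhomology") feature$mh_len else 0L
  if (m > 0) {
    tract <- dep_tail(genome, dep, m)
    genome <- land_write(genome, land, 0L, tract)
    x1 <- dep_cont(genome, dep)
    if (!is.na(x1) && substr(land_head(genome, land, m + 1), m + 1, m + 1) == x1) {
      genome <- land_write(genome, land, m, other_base(x1))
    }
    a2 <- substr(dep_tail(genome, dep, m + 1), 1, 1)
    x2 <- land_upstream(genome, land)
    if (!is.na(x2) && nzchar(a2) && a2 == x2) {
      genome <- land_upstream_write(genome, land, other_base(a2))
    }
  } else if (!is.null(feature) && feature$kind == "templated_insertion") {
    tp <- feature$template_parts
    x1 <- dep_cont(genome, dep)
    p1 <- tp[1, ]
    if (!is.na(x1) && substr(part_seq(genome, p1), 1, 1) == x1) {
      b <- other_base(x1)
      genome <- if (p1$strand == "+") genome_write(genome, p1$chrom, p1$start, b)
                else genome_write(genome, p1$chrom, p1$end, complement1(b))
    }
    pl <- tp[nrow(tp), ]
    x2 <- land_upstream(genome, land)
    ps <- part_seq(genome, pl)
    if (!is.na(x2) && substr(ps, nchar(ps), nchar(ps)) == x2) {
      b <- other_base(x2)
      genome <- if (pl$strand == "+") genome_write(genome, pl$chrom, pl$end, b)
                else genome_write(genome, pl$chrom, pl$start, complement1(b))
    }
    if (nrow(tp) > 1) {
      for (i in seq_len(nrow(tp) - 1)) {
        cb <- part_cont(genome, tp[i, ])
        nxt <- substr(part_seq(genome, tp[i + 1, ]), 1, 1)
        if (!is.na(cb) && cb == nxt) {
          genome <- part_cont_write(genome, tp[i, ], other_base(cb))
        }
        ps <- part_seq(genome, tp[i, ])
        cb2 <- part_cont(genome, flip_part(tp[i + 1, ]))
        nxt2 <- complement1(substr(ps, nchar(ps), nchar(ps)))
        if (!is.na(cb2) && cb2 == nxt2) {
          genome <- part_cont_write(genome, flip_part(tp[i + 1, ]),
                                    other_base(cb2))
        }
      }
    }
  } else if (!is.null(feature) && feature$kind == "untemplated_insertion") {
    # insert content lives in the chain, not the genome; boundary collisions
    # are repaired by substituting the offending insert base
    ins <- feature$insert_seq
    x1 <- dep_cont(genome, dep)
    if (!is.na(x1) && substr(ins, 1, 1) == x1) {
      substr(ins, 1, 1) <- other_base(c(x1, land_upstream(genome, land)))
    }
    x2 <- land_upstream(genome, land)
    if (!is.na(x2) && substr(ins, nchar(ins), nchar(ins)) == x2) {
      substr(ins, nchar(ins), nchar(ins)) <- other_base(c(x2, dep_cont(genome, dep)))
    }
    feature$insert_seq <- ins
  } else {
    x1 <- dep_cont(genome, dep)
    if (!is.na(x1) && land_head(genome, land, 1) == x1) {
      genome <- land_write(genome, land, 0L, other_base(x1))
    }
    x2 <- land_upstream(genome, land)
    if (!is.na(x2) && dep_tail(genome, dep, 1) == x2) {
      genome <- land_upstream_write(genome, land, other_base(dep_tail(genome, dep, 1)))
    }
  }
  list(genome = genome, feature = feature)
}

dep_breakend <- function(dep) {
  if (dep$strand == "+") breakend(dep$chrom, dep$pos, "retains_left", "+")
  else breakend(dep$chrom, dep$pos, "retains_right", "-")
}

land_breakend <- function(land) {
  if (land$strand == "+") breakend(land$chrom, land$pos, "retains_right", "+")
  else breakend(land$chrom, land$pos, "retains_left", "-")
}

event_feature <- function(ev) {
  if (ev$mh_len > 0) {
    junction_feature("microhomology", mh_len = ev$mh_len)
  } else if (nzchar(ev$untemplated_insert)) {
    junction_feature("untemplated_insertion", insert_seq = ev$untemplated_insert)
  } else if (!is.null(ev$templated_insert_sources)) {
    junction_feature("templated_insertion",
                     template_parts = ev$templated_insert_sources)
  } else {
    junction_feature("blunt")
  }
}

# ---- truth model -----------------------------------------------------------

truth_model <- function(genome, derivatives, junctions, truth_cnv) {
  structure(list(genome = genome, derivatives = derivatives,
                 junctions = junctions, truth_cnv = truth_cnv),
            class = "TruthModel")
}

#' @export
print.TruthModel <- function(x, ...) {
  cat(sprintf("TruthModel: %d derivative(s), %d junction(s)\n",
              length(x$derivatives), length(x$junctions)))
  for (d in x$derivatives) {
    cat(sprintf("  der(%s): %d segments, %s bp\n", d$recipient, nrow(d$walk),
                format(nchar(d$seq), big.mark = ",")))
  }
  nz <- x$truth_cnv[x$truth_cnv$cn != x$truth_cnv$baseline, ]
  cat(sprintf("  %d non-baseline copy-number segment(s)\n", nrow(nz)))
  invisible(x)
}

#' Copy-number profile implied by derivative walks
#'
#' Counts, for every reference base, how many times it is traversed by the
#' derivative walks, and adds the intact homologs: a chromosome serving as
#' recipient of a derivative loses one intact copy per derivative built on
#' it, while purely donor chromosomes keep their full baseline.
#'
#' @param walks List of walk data.frames (`chrom`, `start`, `end`,
#'   `strand`), one per derivative.
#' @param genome A [genome_ref()].
#' @param recipients Character vector, the recipient chromosome of each
#'   walk.
#' @return Data.frame of `SegmentCN` rows: `chrom`, `start`, `end`, `cn`,
#'   `baseline` covering every chromosome.
#' @export
walk_cnv <- function(walks, genome, recipients) {
  if (is.data.frame(walks)) walks <- list(walks)
  out <- list()
  for (chrom in names(genome$lengths)) {
    L <- genome$lengths[[chrom]]
    segs <- do.call(rbind, lapply(walks, function(w) w[w$chrom == chrom, , drop = FALSE]))
    cuts <- sort(unique(c(0L, L,
                          if (!is.null(segs) && nrow(segs)) c(segs$start - 1L, segs$end))))
    cuts <- cuts[cuts >= 0 & cuts <= L]
    baseline <- genome$ploidy[[chrom]]
    intact <- baseline - sum(recipients == chrom)
    abort_if(intact < 0, "more derivatives than homologs on %s", chrom)
    starts <- cuts[-length(cuts)] + 1L
    ends <- cuts[-1]
    uses <- vapply(seq_along(starts), function(i) {
      if (is.null(segs) || nrow(segs) == 0) return(0L)
      sum(segs$start <= starts[i] & segs$end >= ends[i])
    }, integer(1))
    cn <- uses + intact
    # merge equal-cn runs
    keep <- c(TRUE, cn[-1] != cn[-length(cn)])
    idx <- cumsum(keep)
    out[[chrom]] <- data.frame(
      chrom = chrom,
      start = tapply(starts, idx, min),
      end = tapply(ends, idx, max),
      cn = cn[keep],
      baseline = baseline,
      row.names = NULL
    )
  }
  res <- do.call(rbind, out)
  res$start <- as.integer(res$start)
  res$end <- as.integer(res$end)
  rownames(res) <- NULL
  res
}

# ---- replicative simulation ------------------------------------------------

# Plan the oriented segment of event k (k < n intermediate, k = n resolution).
plan_segment <- function(genome, chain, k) {
  ev <- chain$events[[k]]
  n <- length(chain$events)
  if (k < n) {
    abort_if(is.na(ev$seg_len) || ev$seg_len < 1,
             "event %d needs a positive seg_len", k)
    if (ev$orientation == "direct") {
      list(chrom = ev$target_chrom, start = ev$target_pos,
           end = ev$target_pos + ev$seg_len - 1L, strand = "+")
    } else {
      list(chrom = ev$target_chrom, start = ev$target_pos - ev$seg_len + 1L,
           end = ev$target_pos, strand = "-")
    }
  } else {
    abort_if(ev$orientation != "direct",
             "the resolution event must rejoin the recipient in direct orientation")
    list(chrom = ev$target_chrom, start = ev$target_pos,
         end = genome$lengths[[ev$target_chrom]], strand = "+")
  }
}

seg_land <- function(seg) {
  if (seg$strand == "+") list(chrom = seg$chrom, pos = seg$start, strand = "+")
  else list(chrom = seg$chrom, pos = seg$end, strand = "-")
}

seg_dep <- function(seg) {
  if (seg$strand == "+") list(chrom = seg$chrom, pos = seg$end, strand = "+")
  else list(chrom = seg$chrom, pos = seg$start, strand = "-")
}

#' Simulate a replicative (FoSTeS/MMBIR) template-switch chain
#'
#' Builds the derivative chromosome produced by iterative template
#' switching, together with ground-truth junctions (whose features encode
#' exactly the requested microhomology / insert signatures) and the
#' implied copy-number profile. Segments copied once beyond baseline
#' appear as duplications, twice as triplications; recipient sequence the
#' fork skips is deleted.
#'
#' With `engineer = TRUE` (the default) the simulator guarantees each
#' requested signature is exactly realizable: for a microhomology joint it
#' first searches landing positions within `search_bp` of the requested
#' target for flanks that already share exactly `mh_len` terminal bases,
#' and otherwise adjusts at most `mh_len + 2` reference bases of the toy
#' genome around the joint; blunt and insert joints get the same
#' anchor-extension guards. With `engineer = FALSE` an unrealizable joint
#' is an explicit error naming the joint - never a silent truncation.
#'
#' @param genome A [genome_ref()] with sequences.
#' @param chain An [event_chain()].
#' @param engineer Adjust landing sites / toy reference so truth labels
#'   are well defined (see Details).
#' @param search_bp Landing-site search window for microhomology joints.
#' @return A `TruthModel`: the (possibly adjusted) genome, one derivative
#'   (recipient, walk, sequence, per-joint metadata), truth junctions and
#'   truth copy-number segments.
#' @export
simulate_replicative <- function(genome, chain, engineer = TRUE,
                                 search_bp = 50L) {
  require_sequence(genome, "simulate_replicative")
  rec <- chain$start$chrom
  abort_if(!rec %in% names(genome$lengths), "unknown recipient chromosome")
  abort_if(chain$start$pos < 1 || chain$start$pos >= genome$lengths[[rec]],
           "chain start outside recipient chromosome")
  n <- length(chain$events)

  # phase 1+2: plan segments joint by joint, searching/engineering as we go
  segs <- vector("list", n + 1)
  feats <- vector("list", n)
  segs[[1]] <- list(chrom = rec, start = 1L, end = chain$start$pos, strand = "+")
  for (k in seq_len(n)) {
    ev <- chain$events[[k]]
    feat <- event_feature(ev)
    dep <- seg_dep(segs[[k]])
    seg <- plan_segment(genome, chain, k)
    abort_if(seg$start < 1 || seg$end > genome$lengths[[seg$chrom]],
             "joint %d: landing segment outside chromosome %s", k, seg$chrom)
    if (feat$kind == "microhomology") {
      abort_if(seg$end - seg$start + 1 <= feat$mh_len,
               "joint %d: segment shorter than requested microhomology", k)
    }
    problem <- check_joint(genome, dep, seg_land(seg), feat)
    if (!is.null(problem) && engineer && feat$kind == "microhomology") {
      # search nearby landing sites where the tract already exists
      found <- FALSE
      for (delta in order(abs(seq(-search_bp, search_bp)))) {
        d <- seq(-search_bp, search_bp)[delta]
        cand <- seg
        cand$start <- seg$start + d
        cand$end <- seg$end + d
        if (cand$start < 1 || cand$end > genome$lengths[[cand$chrom]]) next
        if (k == n) cand$end <- genome$lengths[[cand$chrom]]
        if (is.null(check_joint(genome, dep, seg_land(cand), feat))) {
          seg <- cand
          found <- TRUE
          break
        }
      }
      if (!found) {
        eng <- engineer_joint(genome, dep, seg_land(seg), feat)
        genome <- eng$genome
        feat <- eng$feature
      }
      problem <- check_joint(genome, dep, seg_land(seg), feat)
    } else if (!is.null(problem) && engineer) {
      eng <- engineer_joint(genome, dep, seg_land(seg), feat)
      genome <- eng$genome
      feat <- eng$feature
      problem <- check_joint(genome, dep, seg_land(seg), feat)
    }
    abort_if(!is.null(problem),
             "joint %d not realizable as requested: %s", k, problem)
    segs[[k + 1]] <- seg
    feats[[k]] <- feat
  }

  # phase 3: derivative sequence, joint coordinates, junction records
  der <- genome_seq(genome, rec, 1L, chain$start$pos)
  junctions <- vector("list", n)
  joint_meta <- vector("list", n)
  for (k in seq_len(n)) {
    seg <- segs[[k + 1]]
    feat <- feats[[k]]
    m <- if (feat$kind == "microhomology") feat$mh_len else 0L
    ins <- joint_insert_seq(genome, feat)
    seg_seq <- genome_seq(genome, seg$chrom, seg$start, seg$end, seg$strand)
    joint_end <- nchar(der)
    der <- paste0(der, ins, substr(seg_seq, m + 1L, nchar(seg_seq)))
    junctions[[k]] <- junction(
      id = paste0("J", k),
      a = dep_breakend(seg_dep(segs[[k]])),
      b = land_breakend(seg_land(seg)),
      support = "sequenced",
      feature = feat
    )
    joint_meta[[k]] <- list(derivative = 1L, der_end = joint_end,
                            ins_len = nchar(ins), mh_len = m)
  }
  walk <- do.call(rbind, lapply(segs, function(s) {
    data.frame(chrom = s$chrom, start = s$start, end = s$end, strand = s$strand)
  }))
  truth_cnv <- walk_cnv(list(walk), genome, recipients = rec)
  truth_model(
    genome = genome,
    derivatives = list(list(recipient = rec, walk = walk, seq = der,
                            joints = joint_meta)),
    junctions = junctions,
    truth_cnv = truth_cnv
  )
}

# ---- end-joining simulation ------------------------------------------------

#' Simulate an end-joining (NHEJ/MMEJ) insertional exchange
#'
#' Excises a donor fragment and inserts it at an acceptor locus on another
#' chromosome (or a non-adjacent locus), producing two derivative
#' chromosomes. When `reciprocal_fragment` is given, that fragment moves
#' in the opposite direction (a bidirectional exchange of genetic
#' material); when flank trimming is requested, the trimmed donor bases
#' are lost, leaving a small deletion at the donor locus. Junction
#' signatures are drawn from the end-joining spectrum: blunt ends, 1-3 bp
#' microhomology, or 1-3 bp untemplated inserts.
#'
#' @param genome A [genome_ref()] with sequences.
#' @param donor `list(chrom =, start =, end =)`: excised fragment.
#' @param acceptor `list(chrom =, pos =)`: insertion point (fragment goes
#'   between `pos` and `pos + 1`).
#' @param reciprocal_fragment Optional `list(chrom =, start =, end =)` on
#'   the acceptor chromosome, moved into the donor gap.
#' @param seed Integer seed for the junction-signature draws.
#' @param trim_left,trim_right Donor bases dropped (not reinserted) from
#'   each flank.
#' @param orientation Orientation of the inserted donor fragment.
#' @return A `TruthModel` with two derivatives.
#' @export
simulate_end_joining_insertion <- function(genome, donor, acceptor,
                                           reciprocal_fragment = NULL,
                                           seed = 1L, trim_left = 0L,
                                           trim_right = 0L,
                                           orientation = "direct") {
  require_sequence(genome, "simulate_end_joining_insertion")
  orientation <- match.arg(orientation, c("direct", "inverted"))
  abort_if(donor$chrom == acceptor$chrom &&
             acceptor$pos >= donor$start - 1 && acceptor$pos <= donor$end,
           "acceptor locus must not fall inside the donor fragment")
  if (!is.null(reciprocal_fragment)) {
    abort_if(reciprocal_fragment$chrom == donor$chrom &&
               reciprocal_fragment$start <= donor$end &&
               reciprocal_fragment$end >= donor$start,
             "reciprocal fragment overlaps the donor fragment")
    abort_if(reciprocal_fragment$chrom != acceptor$chrom,
             "reciprocal fragment must come from the acceptor chromosome")
    abort_if(reciprocal_fragment$start != acceptor$pos + 1,
             "the reciprocal fragment is the acceptor material replaced by the insertion; it must start at acceptor pos + 1")
  }
  ins_start <- donor$start + trim_left
  ins_end <- donor$end - trim_right
  abort_if(ins_start > ins_end, "trimming leaves no donor fragment")

  dchrom <- donor$chrom
  achrom <- acceptor$chrom
  Ld <- genome$lengths[[dchrom]]
  La <- genome$lengths[[achrom]]
  abort_if(donor$start <= 1 || donor$end >= Ld,
           "donor fragment must be interstitial")
  abort_if(acceptor$pos < 1 || acceptor$pos >= La,
           "acceptor point outside chromosome")
  frag_strand <- if (orientation == "direct") "+" else "-"

  # walks for the two derivatives; with a reciprocal fragment the donor
  # material replaces it on the acceptor chromosome
  acc_resume <- if (is.null(reciprocal_fragment)) acceptor$pos + 1L
                else reciprocal_fragment$end + 1L
  walk_acc <- data.frame(
    chrom = c(achrom, dchrom, achrom),
    start = c(1L, ins_start, acc_resume),
    end = c(acceptor$pos, ins_end, La),
    strand = c("+", frag_strand, "+")
  )
  if (is.null(reciprocal_fragment)) {
    walk_don <- data.frame(
      chrom = c(dchrom, dchrom),
      start = c(1L, donor$end + 1L),
      end = c(donor$start - 1L, Ld),
      strand = c("+", "+")
    )
  } else {
    rf <- reciprocal_fragment
    walk_don <- data.frame(
      chrom = c(dchrom, achrom, dchrom),
      start = c(1L, rf$start, donor$end + 1L),
      end = c(donor$start - 1L, rf$end, Ld),
      strand = c("+", "+", "+")
    )
  }

  draw_feature <- function() {
    kind <- sample(c("blunt", "microhomology", "untemplated_insertion"), 1,
                   prob = c(0.4, 0.4, 0.2))
    switch(kind,
      blunt = junction_feature("blunt"),
      microhomology = junction_feature("microhomology", mh_len = sample(1:3, 1)),
      untemplated_insertion = junction_feature(
        "untemplated_insertion",
        insert_seq = paste(sample(c("A", "C", "G", "T"), sample(1:3, 1),
                                  replace = TRUE), collapse = "")))
  }

  build <- function(walk) {
    junctions <- list()
    for (k in seq_len(nrow(walk) - 1)) {
      a <- walk[k, ]
      b <- walk[k + 1, ]
      # skip reference-adjacent rows (no junction there)
      if (a$chrom == b$chrom && a$strand == "+" && b$strand == "+" &&
          b$start == a$end + 1) next
      dep <- seg_dep(as.list(a))
      land <- seg_land(as.list(b))
      feat <- draw_feature()
      if (!is.null(check_joint(genome, dep, land, feat))) {
        eng <- engineer_joint(genome, dep, land, feat)
        genome <<- eng$genome
        feat <- eng$feature
      }
      problem <- check_joint(genome, dep, land, feat)
      abort_if(!is.null(problem), "end-joining joint not realizable: %s", problem)
      j <- junction(id = "J0", a = dep_breakend(dep), b = land_breakend(land),
                    support = "sequenced", feature = feat)
      attr(j, "joint_row") <- k
      junctions[[length(junctions) + 1]] <- j
    }
    junctions
  }

  res <- with_seed(seed, {
    j_acc <- build(walk_acc)
    j_don <- build(walk_don)
    list(j_acc = j_acc, j_don = j_don)
  })
  for (i in seq_along(res$j_acc)) res$j_acc[[i]]$id <- paste0("J", i)
  for (i in seq_along(res$j_don)) {
    res$j_don[[i]]$id <- paste0("J", length(res$j_acc) + i)
  }

  seq_of_walk <- function(walk, junctions) {
    feats_by_row <- list()
    for (j in junctions) feats_by_row[[as.character(attr(j, "joint_row"))]] <- j$feature
    der <- genome_seq(genome, walk$chrom[1], walk$start[1], walk$end[1],
                      walk$strand[1])
    metas <- list()
    for (k in seq_len(nrow(walk) - 1)) {
      f <- feats_by_row[[as.character(k)]]
      m <- if (!is.null(f) && f$kind == "microhomology") f$mh_len else 0L
      ins <- joint_insert_seq(genome, f)
      b <- walk[k + 1, ]
      sseq <- genome_seq(genome, b$chrom, b$start, b$end, b$strand)
      if (!is.null(f)) {
        metas[[length(metas) + 1]] <- list(der_end = nchar(der),
                                           ins_len = nchar(ins), mh_len = m)
      }
      der <- paste0(der, ins, substr(sseq, m + 1L, nchar(sseq)))
    }
    list(seq = der, metas = metas)
  }
  sa <- seq_of_walk(walk_acc, res$j_acc)
  sd <- seq_of_walk(walk_don, res$j_don)
  for (i in seq_along(res$j_acc)) {
    sa$metas[[i]]$derivative <- 1L
  }
  for (i in seq_along(res$j_don)) {
    sd$metas[[i]]$derivative <- 2L
  }
  junctions <- c(res$j_acc, res$j_don)
  metas <- c(sa$metas, sd$metas)
  truth_cnv <- walk_cnv(list(walk_acc, walk_don), genome,
                        recipients = c(achrom, dchrom))
  truth_model(
    genome = genome,
    derivatives = list(
      list(recipient = achrom, walk = walk_acc, seq = sa$seq, joints = sa$metas),
      list(recipient = dchrom, walk = walk_don, seq = sd$seq, joints = sd$metas)
    ),
    junctions = junctions,
    truth_cnv = truth_cnv
  )
}

# ---- assay emulation -------------------------------------------------------

#' Emit a probe-level aCGH log2-ratio table
#'
#' Emulates high-density array CGH: one probe every `spacing_bp` bases,
#' log2(copy number / baseline) plus i.i.d. Gaussian noise. Deterministic
#' for a given seed.
#'
#' @param truth A `TruthModel`, or a `SegmentCN` data.frame
#'   (`chrom`, `start`, `end`, `cn`, `baseline`) covering the genome.
#' @param spacing_bp Probe spacing (>= 50).
#' @param noise_sd Gaussian noise standard deviation on the log2 ratio.
#' @param seed Integer seed.
#' @param genome Required when `truth` is a plain data.frame: supplies
#'   chromosome lengths.
#' @param file Optional TSV output path.
#' @return Data.frame with columns `chrom`, `pos`, `log2ratio`.
#' @export
emit_probe_table <- function(truth, spacing_bp = 200L, noise_sd = 0,
                             seed = 1L, genome = NULL, file = NULL) {
  abort_if(spacing_bp < 50, "probe spacing must be >= 50 bp")
  if (inherits(truth, "TruthModel")) {
    cnv <- truth$truth_cnv
    genome <- truth$genome
  } else {
    cnv <- truth
    abort_if(is.null(genome), "supply a genome with a plain SegmentCN table")
  }
  tabs <- lapply(names(genome$lengths), function(chrom) {
    L <- genome$lengths[[chrom]]
    pos <- seq.int(spacing_bp, L, by = spacing_bp)
    segs <- cnv[cnv$chrom == chrom, , drop = FALSE]
    cn <- rep(genome$ploidy[[chrom]], length(pos))
    if (nrow(segs)) {
      idx <- findInterval(pos, segs$start)
      hit <- idx >= 1 & pos <= segs$end[pmax(idx, 1)]
      cn[hit] <- segs$cn[idx[hit]]
    }
    baseline <- genome$ploidy[[chrom]]
    # cn 0 would be -Inf; floor the ratio at 0.05 (deep-loss saturation)
    data.frame(chrom = chrom, pos = pos,
               log2ratio = log2(pmax(cn, 0.05) / baseline))
  })
  tab <- do.call(rbind, tabs)
  if (noise_sd > 0) {
    tab$log2ratio <- tab$log2ratio +
      with_seed(seed, stats::rnorm(nrow(tab), 0, noise_sd))
  }
  rownames(tab) <- NULL
  if (!is.null(file)) {
    utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tab
}

#' Read a probe table written by [emit_probe_table()]
#'
#' @param file TSV path with columns `chrom`, `pos`, `log2ratio`.
#' @return Data.frame.
#' @export
read_probe_table <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Emit junction-spanning reads
#'
#' Emulates Sanger-sequenced long-range PCR products: one record per
#' sequenced junction, `flank_bp` derivative bases on each side of the
#' joint (plus any junctional insert). Hypothetical junctions emit no
#' read. Reads truncated by a derivative end carry a `truncated`
#' attribute.
#'
#' @param truth A `TruthModel`.
#' @param flank_bp Flank length; must be at least twice the largest
#'   microhomology in the truth set.
#' @param file Optional FASTA output path.
#' @return Named character vector of reads (names are junction ids), with
#'   attribute `truncated` (logical vector).
#' @export
emit_junction_reads <- function(truth, flank_bp = 500L, file = NULL) {
  max_mh <- max(c(0L, vapply(truth$junctions, function(j) {
    if (is.null(j$feature)) 0L else j$feature$mh_len
  }, integer(1))))
  abort_if(flank_bp < 2 * max_mh,
           "flank_bp must be at least twice the largest microhomology (%d)", max_mh)
  meta_of <- function(i) {
    # junction i's joint metadata lives in its derivative's joint list
    k <- 0
    for (d in truth$derivatives) {
      for (m in d$joints) {
        k <- k + 1
        if (k == i) return(list(der = d, meta = m))
      }
    }
    NULL
  }
  reads <- character(0)
  trunc <- logical(0)
  k <- 0
  for (i in seq_along(truth$junctions)) {
    j <- truth$junctions[[i]]
    if (j$support != "sequenced") next
    k <- k + 1
    dm <- meta_of(i)
    der <- dm$der$seq
    m <- dm$meta
    lo <- m$der_end - flank_bp + 1L
    hi <- m$der_end + m$ins_len + flank_bp
    was_trunc <- lo < 1 || hi > nchar(der)
    if (was_trunc) {
      warning(sprintf("junction %s closer than flank_bp to a derivative end; read truncated",
                      j$id))
    }
    reads[j$id] <- substr(der, max(1L, lo), min(nchar(der), hi))
    trunc[j$id] <- was_trunc
  }
  attr(reads, "truncated") <- trunc
  if (!is.null(file)) write_fasta(reads, file)
  reads
}

# ---- YAML chain serialization ---------------------------------------------

#' Write / read an event chain as YAML
#'
#' @param chain An [event_chain()].
#' @param file Path.
#' @return `file` invisibly / an [event_chain()].
#' @export
write_event_chain <- function(chain, file) {
  x <- list(
    start = chain$start,
    resolution = chain$resolution,
    seed = chain$seed,
    events = lapply(chain$events, function(ev) {
      e <- list(target_chrom = ev$target_chrom, target_pos = ev$target_pos,
                orientation = ev$orientation, mh_len = ev$mh_len,
                untemplated_insert = ev$untemplated_insert,
                seg_len = if (is.na(ev$seg_len)) NULL else ev$seg_len)
      if (!is.null(ev$templated_insert_sources)) {
        tp <- ev$templated_insert_sources
        e$templated_insert_sources <- lapply(seq_len(nrow(tp)), function(i) {
          as.list(tp[i, c("chrom", "start", "end", "strand")])
        })
      }
      e
    })
  )
  yaml::write_yaml(x, file)
  invisible(file)
}

#' @rdname write_event_chain
#' @export
read_event_chain <- function(file) {
  x <- yaml::read_yaml(file)
  events <- lapply(x$events, function(e) {
    tp <- NULL
    if (!is.null(e$templated_insert_sources)) {
      tp <- do.call(rbind, lapply(e$templated_insert_sources, as.data.frame))
    }
    switch_event(e$target_chrom, e$target_pos, e$orientation,
                 mh_len = e$mh_len %||% 0L,
                 untemplated_insert = e$untemplated_insert %||% "",
                 templated_insert_sources = tp,
                 seg_len = e$seg_len %||% NA)
  })
  event_chain(x$start, events, x$resolution, seed = x$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
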