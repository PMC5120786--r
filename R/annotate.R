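# Junction annotation: map a junction-spanning sequence back onto the
# reference and derive the breakpoint-junction feature taxonomy
# (microhomology length, untemplated insertion, templated insertion with
# template loci). Anchor matching is exact: toy genomes are mutation-free,
# which keeps the simulator/annotator oracle relationship provable.

genome_dna <- function(genome) {
  require_sequence(genome, "junction annotation")
  lapply(genome$sequences, Biostrings::DNAString)
}

ambiguous_error <- function(msg, candidates) {
  stop(errorCondition(
    paste0(msg, ": ", paste(candidates, collapse = ", ")),
    class = c("insmech_ambiguous", "error", "condition")))
}

# Maximal exact extension candidates for the read prefix (toward the joint)
# on both strands of every chromosome. Returns a data.frame of candidates
# with the maximal length only.
prefix_anchor_candidates <- function(read, dna, min_anchor) {
  n <- nchar(read)
  if (n < min_anchor) return(NULL)
  kmer <- substr(read, 1, min_anchor)
  rquery <- Biostrings::DNAString(read)
  out <- list()
  for (chrom in names(dna)) {
    seqc <- dna[[chrom]]
    L <- length(seqc)
    for (g0 in Biostrings::start(Biostrings::matchPattern(kmer, seqc))) {
      win <- Biostrings::subseq(seqc, g0, min(L, g0 + n - 1))
      len <- Biostrings::lcprefix(rquery, win)
      out[[length(out) + 1]] <- data.frame(chrom = chrom, strand = "+",
                                           len = len, joint_pos = g0 + len - 1)
    }
    rkmer <- revcomp(kmer)
    for (h0 in Biostrings::start(Biostrings::matchPattern(rkmer, seqc))) {
      h_end <- h0 + min_anchor - 1
      win <- Biostrings::reverseComplement(
        Biostrings::subseq(seqc, max(1, h_end - n + 1), h_end))
      len <- Biostrings::lcprefix(rquery, win)
      out[[length(out) + 1]] <- data.frame(chrom = chrom, strand = "-",
                                           len = len, joint_pos = h_end - len + 1)
    }
  }
  if (length(out) == 0) return(NULL)
  cand <- do.call(rbind, out)
  cand[cand$len == max(cand$len), , drop = FALSE]
}

suffix_anchor_candidates <- function(read, dna, min_anchor) {
  n <- nchar(read)
  if (n < min_anchor) return(NULL)
  kmer <- substr(read, n - min_anchor + 1, n)
  rquery <- Biostrings::DNAString(read)
  out <- list()
  for (chrom in names(dna)) {
    seqc <- dna[[chrom]]
    L <- length(seqc)
    for (g0 in Biostrings::start(Biostrings::matchPattern(kmer, seqc))) {
      g_end <- g0 + min_anchor - 1
      win <- Biostrings::subseq(seqc, max(1, g_end - n + 1), g_end)
      len <- Biostrings::lcsuffix(rquery, win)
      out[[length(out) + 1]] <- data.frame(chrom = chrom, strand = "+",
                                           len = len, joint_pos = g_end - len + 1)
    }
    rkmer <- revcomp(kmer)
    for (h0 in Biostrings::start(Biostrings::matchPattern(rkmer, seqc))) {
      win <- Biostrings::reverseComplement(
        Biostrings::subseq(seqc, h0, min(L, h0 + n - 1)))
      len <- Biostrings::lcsuffix(rquery, win)
      out[[length(out) + 1]] <- data.frame(chrom = chrom, strand = "-",
                                           len = len, joint_pos = h0 + len - 1)
    }
  }
  if (length(out) == 0) return(NULL)
  cand <- do.call(rbind, out)
  cand[cand$len == max(cand$len), , drop = FALSE]
}

#' Locate the two breakends spanned by a junction read
#'
#' Finds the maximal exact prefix anchor and maximal exact suffix anchor
#' of the read in the reference (either strand, any chromosome) and
#' returns the two breakends plus the unaligned middle. When the anchors
#' overlap, the overlap is the junctional microhomology and `middle` is
#' empty; breakend positions then sit at the outer tract boundaries, so
#' the shared tract is included in both retained flanks.
#'
#' @param read_seq Junction-spanning nucleotide string.
#' @param genome A [genome_ref()] with sequences.
#' @param min_anchor Minimum exact anchor length on each end (default 30).
#' @return `list(a, b, middle, overlap, prefix_len, suffix_len)` with
#'   [breakend()]s `a` (prefix side) and `b` (suffix side).
#' @export
locate_breakends <- function(read_seq, genome, min_anchor = 30L) {
  dna <- genome_dna(genome)
  n <- nchar(read_seq)
  abort_if(n < 2 * min_anchor, "read shorter than two anchors")
  pre <- prefix_anchor_candidates(read_seq, dna, min_anchor)
  abort_if(is.null(pre), "no prefix anchor of %d bp found in the genome", min_anchor)
  suf <- suffix_anchor_candidates(read_seq, dna, min_anchor)
  abort_if(is.null(suf), "no suffix anchor of %d bp found in the genome", min_anchor)
  if (nrow(pre) > 1) {
    ambiguous_error("prefix anchor placement is ambiguous",
                    sprintf("%s:%d(%s)", pre$chrom, pre$joint_pos, pre$strand))
  }
  if (nrow(suf) > 1) {
    ambiguous_error("suffix anchor placement is ambiguous",
                    sprintf("%s:%d(%s)", suf$chrom, suf$joint_pos, suf$strand))
  }
  Lp <- pre$len
  Ls <- suf$len
  a <- if (pre$strand == "+") breakend(pre$chrom, pre$joint_pos, "retains_left", "+")
       else breakend(pre$chrom, pre$joint_pos, "retains_right", "-")
  b <- if (suf$strand == "+") breakend(suf$chrom, suf$joint_pos, "retains_right", "+")
       else breakend(suf$chrom, suf$joint_pos, "retains_left", "-")
  middle_len <- (n - Ls) - Lp
  if (Lp >= n || Ls >= n) stop("no junction found: read is reference-collinear")
  if (middle_len == 0 && a$chrom == b$chrom && a$strand == b$strand) {
    collinear <- (a$strand == "+" && b$pos == a$pos + 1) ||
      (a$strand == "-" && b$pos == a$pos - 1)
    if (collinear) stop("no junction found: read is reference-collinear")
  }
  middle <- if (middle_len > 0) substr(read_seq, Lp + 1, n - Ls) else ""
  list(a = a, b = b, middle = middle,
       overlap = max(0L, -middle_len),
       prefix_len = Lp, suffix_len = Ls)
}

# map breakends to the oriented flank descriptors used by the simulator
breakend_as_dep <- function(be) {
  if (be$side == "retains_left") list(chrom = be$chrom, pos = be$pos, strand = "+")
  else list(chrom = be$chrom, pos = be$pos, strand = "-")
}

breakend_as_land <- function(be) {
  if (be$side == "retains_right") list(chrom = be$chrom, pos = be$pos, strand = "+")
  else list(chrom = be$chrom, pos = be$pos, strand = "-")
}

#' Measure junctional microhomology between two breakends
#'
#' Returns the maximal k >= 0 such that the k bases at the joint are
#' identical in both reference flanks (read in derivative orientation) and
#' therefore present once in the derivative; 0 means blunt ends.
#' Microhomology is measured on the derivative joint, so inverted joins
#' compare reverse-complemented flanks.
#'
#' @param a,b [breakend()]s (`a` entering the joint, `b` leaving it), with
#'   positions at the outer tract boundaries as returned by
#'   [locate_breakends()].
#' @param genome A [genome_ref()] with sequences.
#' @param read_seq Optional junction read (unused by the computation;
#'   accepted for interface symmetry).
#' @param max_mh Search cap.
#' @return Integer microhomology length.
#' @export
measure_microhomology <- function(a, b, genome, read_seq = NULL, max_mh = 100L) {
  dep <- breakend_as_dep(a)
  land <- breakend_as_land(b)
  # the length-k flank tails/heads agree only at k equal to the shared
  # tract length, so take the maximum over all k rather than stopping at
  # the first mismatch
  best <- 0L
  for (k in seq_len(max_mh)) {
    ta <- tryCatch(dep_tail(genome, dep, k), error = function(e) NULL)
    tb <- tryCatch(land_head(genome, land, k), error = function(e) NULL)
    if (is.null(ta) || is.null(tb)) break
    if (ta == tb) best <- k
  }
  best
}

#' Classify the unaligned middle of a junction read
#'
#' An empty middle is blunt (or microhomology when the anchors overlap). A
#' non-empty middle is greedily decomposed left-to-right into maximal
#' exact genome matches of at least `min_template_len` bases (either
#' strand, any chromosome); the longest match wins, and ties are broken in
#' favour of loci within `near_window_bp` of either breakend, then by
#' chromosome name, coordinate, and `+` strand. A fully or partially
#' decomposed middle is a templated insertion with ordered template parts
#' (a warning flags unmatched remainders of at least `min_template_len`
#' bases); a middle with no qualifying match is an untemplated insertion.
#'
#' @param middle Unaligned middle sequence from [locate_breakends()].
#' @param genome A [genome_ref()] with sequences.
#' @param near_window_bp Window around the breakends searched
#'   preferentially (tie-break only).
#' @param min_template_len Minimum exact match qualifying as templated.
#' @param breakends Optional `list(a, b)` of [breakend()]s for the window
#'   tie-break.
#' @param mh_len Anchor overlap, used when `middle` is empty.
#' @return A [junction_feature()].
#' @export
classify_insert <- function(middle, genome, near_window_bp = 20000L,
                            min_template_len = 10L, breakends = NULL,
                            mh_len = 0L) {
  if (!nzchar(middle)) {
    if (mh_len > 0) return(junction_feature("microhomology", mh_len = mh_len))
    return(junction_feature("blunt"))
  }
  dna <- genome_dna(genome)
  n <- nchar(middle)
  in_window <- function(chrom, start, end) {
    if (is.null(breakends)) return(FALSE)
    any(vapply(breakends, function(be) {
      be$chrom == chrom && start <= be$pos + near_window_bp &&
        end >= be$pos - near_window_bp
    }, logical(1)))
  }
  i <- 1L
  parts <- list()
  unmatched <- 0L
  while (i <= n) {
    rest <- substr(middle, i, n)
    cand <- prefix_anchor_candidates(rest, dna, min_template_len)
    if (is.null(cand) || max(cand$len) < min_template_len) {
      unmatched <- unmatched + 1L
      i <- i + 1L
      next
    }
    len <- cand$len[1]
    cand$start <- ifelse(cand$strand == "+", cand$joint_pos - len + 1, cand$joint_pos)
    cand$end <- ifelse(cand$strand == "+", cand$joint_pos, cand$joint_pos + len - 1)
    cand$near <- mapply(in_window, cand$chrom, cand$start, cand$end)
    cand <- cand[order(!cand$near, cand$chrom, cand$start, cand$strand != "+"), ]
    best <- cand[1, ]
    parts[[length(parts) + 1]] <- data.frame(chrom = best$chrom,
                                             start = best$start,
                                             end = best$end,
                                             strand = best$strand)
    i <- i + len
  }
  if (length(parts) == 0) {
    return(junction_feature("untemplated_insertion", insert_seq = middle))
  }
  if (unmatched >= min_template_len) {
    warning(sprintf(
      "mixed junction insert: %d bp could not be assigned to a template locus",
      unmatched))
  }
  junction_feature("templated_insertion", insert_seq = middle,
                   template_parts = do.call(rbind, parts),
                   unmatched = unmatched)
}

#' Annotate a junction-spanning read
#'
#' Composes [locate_breakends()], [measure_microhomology()] and
#' [classify_insert()]. Reads are canonicalized so the prefix anchor maps
#' to the reference `+` strand, making annotation idempotent under
#' reverse complement of the input. Ambiguous anchor placement (e.g. both
#' copies of a low copy repeat) yields an unresolved junction rather than
#' an error.
#'
#' @param read_seq Junction-spanning sequence.
#' @param genome A [genome_ref()] with sequences.
#' @param config List of thresholds: `min_anchor`, `min_template_len`,
#'   `near_window_bp`.
#' @param id Junction id for the output record.
#' @return A [junction()]; unresolved junctions carry no feature and are
#'   flagged.
#' @export
annotate_junction <- function(read_seq, genome, config = list(), id = "J") {
  cfg <- utils::modifyList(list(min_anchor = 30L, min_template_len = 10L,
                                near_window_bp = 20000L), config)
  annotate_once <- function(rs) {
    loc <- tryCatch(
      locate_breakends(rs, genome, cfg$min_anchor),
      insmech_ambiguous = function(e) NULL
    )
    if (is.null(loc)) return(NULL)
    feature <- classify_insert(loc$middle, genome,
                               near_window_bp = cfg$near_window_bp,
                               min_template_len = cfg$min_template_len,
                               breakends = list(loc$a, loc$b),
                               mh_len = loc$overlap)
    junction(id, a = loc$a, b = loc$b, read_seq = rs,
             support = "sequenced", feature = feature)
  }
  # evaluate both read orientations and keep a deterministic canonical one,
  # so annotation is invariant under reverse complement of the input
  cands <- list(annotate_once(read_seq), annotate_once(revcomp(read_seq)))
  cands <- Filter(Negate(is.null), cands)
  if (length(cands) == 0) {
    return(junction(id, a = NULL, b = NULL, read_seq = read_seq,
                    support = "sequenced", feature = NULL, unresolved = TRUE))
  }
  key <- vapply(cands, function(j) {
    sprintf("%d|%s|%012d|%s|%012d", as.integer(j$a$strand != "+"),
            j$a$chrom, j$a$pos, j$b$chrom, j$b$pos)
  }, character(1))
  cands[[order(key)[1]]]
}

#' Annotate a set of junction reads
#'
#' @param reads Named character vector of reads (as from
#'   [emit_junction_reads()]) or a FASTA path.
#' @param genome A [genome_ref()] with sequences.
#' @param config See [annotate_junction()].
#' @return List of [junction()]s, named by read id.
#' @export
annotate_junctions <- function(reads, genome, config = list()) {
  if (length(reads) == 1 && file.exists(reads)) reads <- read_fasta(reads)
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("J", seq_along(reads))
  out <- lapply(seq_along(reads), function(i) {
    annotate_junction(reads[[i]], genome, config, id = ids[i])
  })
  names(out) <- ids
  out
}
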