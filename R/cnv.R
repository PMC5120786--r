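# Copy-number segmentation and the per-chromosome pattern vocabulary
# (DUP/TRP/DEL/NML strings, DUP-TRP/INV-DUP recognition). Segmentation is a
# simple deterministic change-point routine: the scientific content of this
# package sits downstream of segmentation, so a z-tested greedy binary
# split with integer-CN snapping is sufficient at toy scale.

robust_noise_sd <- function(x) {
  if (length(x) < 2) return(1e-3)
  # successive differences of i.i.d. Gaussian noise have sd sqrt(2)*sd(noise)
  m <- stats::median(abs(diff(x)))
  max(m / (sqrt(2) * stats::qnorm(0.75)), 1e-3)
}

split_points <- function(x, i, j, min_probes, z_thresh, sd_hat) {
  n <- j - i + 1
  if (n < 2 * min_probes) return(integer(0))
  xs <- x[i:j]
  cs <- cumsum(xs)
  tot <- cs[n]
  ks <- min_probes:(n - min_probes)
  ml <- cs[ks] / ks
  mr <- (tot - cs[ks]) / (n - ks)
  z <- abs(ml - mr) / (sd_hat * sqrt(1 / ks + 1 / (n - ks)))
  if (max(z) <= z_thresh) return(integer(0))
  k <- i + ks[which.max(z)] - 1  # last index of the left part
  c(split_points(x, i, k, min_probes, z_thresh, sd_hat), k,
    split_points(x, k + 1, j, min_probes, z_thresh, sd_hat))
}

#' Segment a probe-level log2-ratio table into copy-number states
#'
#' Greedy binary change-point splitting on the mean log2 ratio, with each
#' candidate split z-tested against a robust noise estimate; final
#' segments are snapped to the nearest integer copy number and adjacent
#' equal-CN segments merged. Deterministic. Chromosomes with fewer than
#' `min_probes` probes yield a single baseline segment with a warning.
#'
#' @param probes Data.frame with columns `chrom`, `pos`, `log2ratio`,
#'   sorted by position within chromosome.
#' @param min_probes Minimum probes per segment (default 5).
#' @param z_thresh z threshold for accepting a split (default 4).
#' @param genome Optional [genome_ref()] supplying per-chromosome ploidy
#'   baselines (never inferred from the data); default baseline 2.
#' @return Data.frame of `SegmentCN` rows (`chrom`, `start`, `end`, `cn`,
#'   `baseline`) covering each chromosome's probe extent; segment
#'   boundaries fall midway between flanking probes.
#' @export
segment_probes <- function(probes, min_probes = 5L, z_thresh = 4,
                           genome = NULL) {
  out <- list()
  for (chrom in unique(probes$chrom)) {
    p <- probes[probes$chrom == chrom, ]
    abort_if(is.unsorted(p$pos), "probes on %s are not sorted", chrom)
    baseline <- if (!is.null(genome)) genome$ploidy[[chrom]] else 2L
    if (nrow(p) < min_probes) {
      warning(sprintf("chromosome %s has fewer than %d probes; reporting baseline",
                      chrom, min_probes))
      out[[chrom]] <- data.frame(chrom = chrom, start = min(p$pos),
                                 end = max(p$pos), cn = baseline,
                                 baseline = baseline)
      next
    }
    x <- p$log2ratio
    sd_hat <- robust_noise_sd(x)
    cuts <- split_points(x, 1L, nrow(p), min_probes, z_thresh, sd_hat)
    lo <- c(1L, cuts + 1L)
    hi <- c(cuts, nrow(p))
    cn <- vapply(seq_along(lo), function(s) {
      max(0L, as.integer(round(2 ^ mean(x[lo[s]:hi[s]]) * baseline)))
    }, integer(1))
    keep <- c(TRUE, cn[-1] != cn[-length(cn)])
    lo <- lo[keep]
    hi <- c(lo[-1] - 1L, nrow(p))
    cn <- cn[keep]
    # contiguous coordinates with boundaries midway between flanking probes
    starts <- c(p$pos[1],
                if (length(lo) > 1) (p$pos[hi[-length(hi)]] + p$pos[lo[-1]]) %/% 2 + 1)
    ends <- c(if (length(lo) > 1) (p$pos[hi[-length(hi)]] + p$pos[lo[-1]]) %/% 2,
              p$pos[nrow(p)])
    out[[chrom]] <- data.frame(chrom = chrom, start = as.integer(starts),
                               end = as.integer(ends), cn = cn,
                               baseline = baseline)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Derive DEL/DUP/TRP calls from copy-number segments
#'
#' DEL is any loss below baseline, DUP a single extra copy, TRP two extra
#' copies (higher states are labelled AMP). Sizes use the closed-interval
#' convention (`end - start + 1`).
#'
#' @param segments `SegmentCN` data.frame from [segment_probes()] or
#'   [walk_cnv()].
#' @return Data.frame of `CNVCall` rows: `chrom`, `start`, `end`, `type`,
#'   `cn`, `baseline`, `size_bp`.
#' @export
cnv_calls <- function(segments) {
  seg <- segments[segments$cn != segments$baseline, , drop = FALSE]
  if (nrow(seg) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), type = character(0), cn = integer(0),
                      baseline = integer(0), size_bp = integer(0)))
  }
  seg$type <- ifelse(seg$cn < seg$baseline, "DEL",
                     ifelse(seg$cn == seg$baseline + 1, "DUP",
                            ifelse(seg$cn == seg$baseline + 2, "TRP", "AMP")))
  seg$size_bp <- interval_length(seg$start, seg$end)
  rownames(seg) <- NULL
  seg[, c("chrom", "start", "end", "type", "cn", "baseline", "size_bp")]
}

#' Per-chromosome copy-number pattern string
#'
#' Hyphen-joined ordered CNV states along a chromosome, with `NML`
#' interposed wherever consecutive calls are separated by a gap, e.g.
#' `"DUP-NML-DEL-NML-DEL"`. No calls yields `"NML"`.
#'
#' @param calls `CNVCall` data.frame from [cnv_calls()].
#' @param chrom Chromosome to summarize.
#' @param gap_tol Gaps of at most this many bases between consecutive
#'   calls are treated as contiguous (default 0).
#' @return A pattern string.
#' @export
pattern_string <- function(calls, chrom, gap_tol = 0L) {
  cc <- calls[calls$chrom == chrom, , drop = FALSE]
  if (nrow(cc) == 0) return("NML")
  cc <- cc[order(cc$start), ]
  states <- cc$type[1]
  if (nrow(cc) > 1) {
    for (i in 2:nrow(cc)) {
      gap <- cc$start[i] - cc$end[i - 1] - 1L
      if (gap > gap_tol) states <- c(states, "NML")
      states <- c(states, cc$type[i])
    }
  }
  paste(states, collapse = "-")
}

#' Parse a pattern string back into ordered states
#'
#' @param pattern String as produced by [pattern_string()].
#' @return Character vector of states.
#' @export
parse_pattern <- function(pattern) strsplit(pattern, "-", fixed = TRUE)[[1]]

junction_is_inverted <- function(j) {
  !is.null(j$a) && !is.null(j$b) && j$a$side == j$b$side
}

#' Detect a DUP-TRP/INV-DUP pattern
#'
#' TRUE when a triplicated segment is embedded inside a duplicated region
#' (the copy-number gains are contiguous and extend beyond the TRP on both
#' sides) and at least one junction with inverted orientation (both
#' breakends retaining the same flank side) has a breakend at a boundary
#' of the triplication or of the containing duplication.
#'
#' @param calls `CNVCall` data.frame restricted to one chromosome.
#' @param junctions List of [junction()]s.
#' @param slop_bp Boundary-matching tolerance (default 5).
#' @return `list(detected, trp, dup_region, junction_id)`.
#' @export
detect_dup_trp_inv_dup <- function(calls, junctions, slop_bp = 5L) {
  abort_if(length(unique(calls$chrom)) > 1,
           "detect_dup_trp_inv_dup expects calls on a single chromosome")
  gains <- calls[calls$type %in% c("DUP", "TRP"), , drop = FALSE]
  trps <- gains[gains$type == "TRP", , drop = FALSE]
  no <- list(detected = FALSE, trp = NULL, dup_region = NULL, junction_id = NULL)
  if (nrow(trps) == 0 || nrow(gains) < 2) return(no)
  gains <- gains[order(gains$start), ]
  # merge contiguous gain runs
  run_id <- cumsum(c(TRUE, gains$start[-1] - gains$end[-nrow(gains)] - 1L > slop_bp))
  for (t in seq_len(nrow(trps))) {
    trp <- trps[t, ]
    rid <- run_id[gains$start == trp$start & gains$end == trp$end][1]
    run <- gains[run_id == rid, ]
    region <- c(min(run$start), max(run$end))
    embedded <- any(run$type == "DUP" & run$end < trp$start + slop_bp) &&
      any(run$type == "DUP" & run$start > trp$end - slop_bp)
    contained <- region[1] < trp$start && region[2] > trp$end
    if (!(embedded && contained)) next
    boundaries <- c(trp$start, trp$end, region)
    for (j in junctions) {
      if (!junction_is_inverted(j)) next
      for (be in list(j$a, j$b)) {
        if (be$chrom == trp$chrom && any(abs(be$pos - boundaries) <= slop_bp)) {
          return(list(detected = TRUE, trp = trp, dup_region = region,
                      junction_id = j$id))
        }
      }
    }
  }
  no
}

#' Export CNV calls as BED (0-based half-open) and TSV (1-based closed)
#'
#' @param calls `CNVCall` data.frame.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_calls_bed <- function(calls, file) {
  header <- "# BED: 0-based half-open coordinates"
  lines <- sprintf("%s\t%d\t%d\t%s", calls$chrom, calls$start - 1L, calls$end,
                   calls$type)
  writeLines(c(header, lines), file)
  invisible(file)
}

#' @rdname write_calls_bed
#' @export
write_calls_tsv <- function(calls, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# coordinates: 1-based, fully closed", con)
  utils::write.table(calls, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
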