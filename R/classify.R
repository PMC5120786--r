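# Mechanism classification: encode the molecular criteria separating basic
# complex insertions (end joining or a single template switch) from
# chromothripsis-like chromoanasynthesis (iterative replicative template
# switching), plus the balanced bidirectional exchange category. Rules are
# disjunctive on positive evidence: blunt junctions never veto a
# replicative call, since replicative CGRs routinely include blunt or
# short-microhomology joints.

#' Aggregate case-level features for mechanism classification
#'
#' @param model Optional `DerivativeModel` (its junction list, including
#'   hypothetical junctions, supplements `junctions`).
#' @param calls `CNVCall` data.frame (from [cnv_calls()]).
#' @param junctions List of [junction()]s; unresolved junctions are
#'   excluded from the microhomology maximum.
#' @param metadata Optional list; `de_novo` may be `"yes"`, `"no"` or
#'   `"unknown"`.
#' @param small_cnv_max CNVs at or below this size (bp) still count as
#'   "apparently balanced" flanking changes (default 10 kb).
#' @param slop_bp Boundary tolerance for the insertion-site-deletion test.
#' @return An object of class `CaseFeatures`.
#' @export
extract_features <- function(model = NULL, calls, junctions,
                             metadata = list(), small_cnv_max = 10000L,
                             slop_bp = 5L) {
  all_j <- junctions
  if (!is.null(model)) {
    have <- vapply(all_j, `[[`, character(1), "id")
    for (j in model$junctions_used) {
      if (!j$id %in% have) all_j <- c(all_j, list(j))
    }
  }
  resolved <- Filter(function(j) !is.null(j$feature), all_j)
  feats <- lapply(resolved, `[[`, "feature")
  gains <- calls[calls$type %in% c("DUP", "TRP"), , drop = FALSE]
  n_templated <- sum(vapply(feats, function(f) f$kind == "templated_insertion",
                            logical(1)))
  tlens <- vapply(feats, function(f) {
    if (f$kind == "templated_insertion") feature_insert_len(f) else 0L
  }, integer(1))
  chroms <- unique(c(
    calls$chrom,
    unlist(lapply(all_j, function(j) {
      c(if (!is.null(j$a)) j$a$chrom, if (!is.null(j$b)) j$b$chrom)
    })),
    unlist(lapply(feats, function(f) {
      if (!is.null(f$template_parts)) f$template_parts$chrom
    }))
  ))
  dtid <- FALSE
  for (chrom in unique(calls$chrom)) {
    d <- detect_dup_trp_inv_dup(calls[calls$chrom == chrom, , drop = FALSE],
                                all_j, slop_bp = max(slop_bp, 5L))
    if (d$detected) dtid <- TRUE
  }
  dels <- calls[calls$type == "DEL", , drop = FALSE]
  del_at_site <- FALSE
  if (nrow(dels)) {
    for (i in seq_len(nrow(dels))) {
      de <- dels[i, ]
      for (j in all_j) {
        if (is.null(j$a) || is.null(j$b)) next
        ends <- list(j$a, j$b)
        for (k in 1:2) {
          be <- ends[[k]]
          mate <- ends[[3 - k]]
          at_boundary <- be$chrom == de$chrom &&
            min(abs(be$pos - c(de$start - 1L, de$start, de$end, de$end + 1L))) <= slop_bp
          mate_leaves <- mate$chrom != de$chrom ||
            mate$pos < de$start - slop_bp || mate$pos > de$end + slop_bp
          # the mate must leave the deletion locus entirely (a plain
          # deletion junction joins the two flanks of the same DEL)
          mate_is_flank <- mate$chrom == de$chrom &&
            min(abs(mate$pos - c(de$start - 1L, de$end + 1L))) <= slop_bp
          if (at_boundary && mate_leaves && !mate_is_flank) del_at_site <- TRUE
        }
      }
    }
  }
  structure(list(
    n_gains = nrow(gains),
    has_trp = any(calls$type == "TRP"),
    has_dup_trp_inv_dup = dtid,
    max_mh = max(c(0L, vapply(feats, `[[`, integer(1), "mh_len"))),
    n_templated_insertions = n_templated,
    max_templated_len = max(c(0L, tlens)),
    n_chromosomes = max(1L, length(chroms)),
    n_junctions = length(all_j),
    net_balanced = nrow(calls) == 0 || all(calls$size_bp <= small_cnv_max),
    deletion_at_insertion_site = del_at_site,
    de_novo = metadata$de_novo %||% "unknown"
  ), class = "CaseFeatures")
}

#' @export
print.CaseFeatures <- function(x, ...) {
  cat("CaseFeatures:\n")
  for (nm in names(unclass(x))) cat(sprintf("  %s = %s\n", nm, x[[nm]]))
  invisible(x)
}

#' Classify the generative mechanism of a complex insertion
#'
#' Deterministic rule cascade over [extract_features()] output:
#' \enumerate{
#'   \item chromoanasynthesis when multiple copy-number gains (or a
#'     triplication) co-occur with replicative junction signatures
#'     (microhomology longer than `mh_cutoff`, or any templated
#'     insertion);
#'   \item chromoanasynthesis (flagged as outside the observed spectrum)
#'     when any gain co-occurs with a templated insertion;
#'   \item basic complex insertion when a single duplication inserts into
#'     a deletion with only short-microhomology / small-insert junctions;
#'   \item balanced end-joining exchange when no copy-number gain exists
#'     and all residual CNVs are small flanking changes (MMEJ tolerates
#'     substantial microhomology, so no microhomology cap applies here);
#'   \item otherwise unclassified.
#' }
#' `de_novo` status is reported in the evidence trail but never used by
#' the cascade: it is pedigree metadata, not molecular signal.
#'
#' @param features A `CaseFeatures`.
#' @param thresholds List: `mh_cutoff` (default 4) and `basic_mh_max`
#'   (default 3).
#' @return An object of class `MechanismCall` with `label`, `evidence`
#'   (every rule consulted, with its observed value), `proposed_repair`
#'   and `notes`.
#' @export
classify_mechanism <- function(features, thresholds = list()) {
  th <- utils::modifyList(list(mh_cutoff = 4L, basic_mh_max = 3L), thresholds)
  abort_if(th$mh_cutoff < 0 || th$mh_cutoff > 50, "mh_cutoff outside sane range")
  abort_if(th$basic_mh_max < 0 || th$basic_mh_max > 50,
           "basic_mh_max outside sane range")
  f <- features
  ev <- list()
  note <- character(0)
  add_ev <- function(criterion, value, satisfied) {
    ev[[length(ev) + 1]] <<- data.frame(criterion = criterion,
                                        value = as.character(value),
                                        satisfied = satisfied)
  }
  multi_gain <- f$n_gains >= 2 || f$has_trp
  repl_sig <- f$max_mh > th$mh_cutoff || f$n_templated_insertions >= 1
  add_ev("multiple copy-number gains or triplication",
         sprintf("n_gains=%d, has_trp=%s", f$n_gains, f$has_trp), multi_gain)
  add_ev(sprintf("replicative junction signature (mh > %d or templated insert)",
                 th$mh_cutoff),
         sprintf("max_mh=%d, n_templated=%d", f$max_mh, f$n_templated_insertions),
         repl_sig)
  add_ev("DUP-TRP/INV-DUP pattern", f$has_dup_trp_inv_dup, f$has_dup_trp_inv_dup)
  label <- NULL
  if (multi_gain && repl_sig) {
    label <- "chromoanasynthesis"
  } else if (f$n_gains >= 1 && f$n_templated_insertions >= 1) {
    label <- "chromoanasynthesis"
    note <- c(note, "single gain with templated insertion: outside the observed spectrum, assigned to the replicative class")
    add_ev("any gain with templated insertion",
           sprintf("n_gains=%d, n_templated=%d", f$n_gains,
                   f$n_templated_insertions), TRUE)
  }
  if (is.null(label)) {
    basic <- f$n_gains == 1 && !f$has_trp && f$deletion_at_insertion_site &&
      f$max_mh <= th$basic_mh_max && f$n_templated_insertions == 0
    add_ev(sprintf("single duplication into a deletion with mh <= %d and no templated insert",
                   th$basic_mh_max),
           sprintf("n_gains=%d, has_trp=%s, del_at_site=%s, max_mh=%d",
                   f$n_gains, f$has_trp, f$deletion_at_insertion_site,
                   f$max_mh), basic)
    if (basic) label <- "basic_complex_insertion"
  }
  if (is.null(label)) {
    balanced <- f$net_balanced && f$n_gains == 0
    add_ev("net balanced (small flanking CNVs only) with no copy-number gain",
           sprintf("net_balanced=%s, n_gains=%d", f$net_balanced, f$n_gains),
           balanced)
    if (balanced) label <- "balanced_end_joining_exchange"
  }
  if (is.null(label)) label <- "unclassified"
  add_ev("de novo status (metadata only, not used by the cascade)",
         f$de_novo, NA)
  repair <- switch(label,
    chromoanasynthesis = "FoSTeS/MMBIR-iterative",
    basic_complex_insertion = if (f$max_mh >= 2) "MMEJ" else "NHEJ",
    balanced_end_joining_exchange = if (f$max_mh >= 2) "MMEJ" else "NHEJ",
    NA_character_)
  if (label == "basic_complex_insertion") {
    note <- c(note, "NHEJ, MMEJ and FoSTeS/MMBIR with a single template switch are all compatible with this signature")
  }
  structure(list(label = label, evidence = do.call(rbind, ev),
                 proposed_repair = repair, notes = note),
            class = "MechanismCall")
}

#' @export
print.MechanismCall <- function(x, ...) {
  cat(sprintf("MechanismCall: %s (proposed repair: %s)\n", x$label,
              x$proposed_repair))
  print(x$evidence, row.names = FALSE)
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}

#' Annotate breakends with repeat-element context
#'
#' Looks up each breakend in a user-supplied repeat annotation (BED with a
#' name column, e.g. a RepeatMasker track export) and reports the name of
#' the containing repeat, or `"-"` when none contains it.
#'
#' @param junctions List of [junction()]s.
#' @param repeat_bed Path to a BED file, or a `GRanges` with a `name`
#'   column.
#' @return Data.frame with one row per breakend: `junction`, `end`,
#'   `chrom`, `pos`, `repeat_name`.
#' @export
annotate_repeats <- function(junctions, repeat_bed) {
  gr <- if (is.character(repeat_bed)) rtracklayer::import(repeat_bed)
        else repeat_bed
  rows <- list()
  for (j in junctions) {
    for (endname in c("a", "b")) {
      be <- j[[endname]]
      if (is.null(be)) next
      label <- "-"
      if (length(gr)) {
        q <- GenomicRanges::GRanges(be$chrom, IRanges::IRanges(be$pos, be$pos))
        hits <- GenomicRanges::findOverlaps(q, gr)
        if (length(hits)) {
          label <- as.character(gr$name[S4Vectors::subjectHits(hits)[1]])
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        junction = j$id, end = endname, chrom = be$chrom, pos = be$pos,
        repeat_name = label)
    }
  }
  do.call(rbind, rows)
}
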