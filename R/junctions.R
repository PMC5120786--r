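#' Breakend of a junction
#'
#' A breakend is one end of a novel adjacency. `side` records which
#' reference flank survives into the derivative: `"retains_left"` keeps
#' the bases at and below `pos`, `"retains_right"` keeps the bases at and
#' above `pos`. `strand` records the orientation in which that flank is
#' read in the derivative (`"+"` reference forward, `"-"` reverse
#' complement); side and strand jointly give the four canonical breakend
#' orientations.
#'
#' @param chrom Chromosome name.
#' @param pos 1-based position; with microhomology the shared tract is
#'   included in both flanks, so `pos` sits at the tract boundary.
#' @param side `"retains_left"` or `"retains_right"`.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `BreakEnd`.
#' @export
breakend <- function(chrom, pos, side, strand = "+") {
  side <- match.arg(side, c("retains_left", "retains_right"))
  abort_if(!strand %in% c("+", "-"), "bad strand")
  structure(list(chrom = chrom, pos = as.integer(pos), side = side,
                 strand = strand),
            class = "BreakEnd")
}

#' @export
format.BreakEnd <- function(x, ...) {
  arrow <- if (x$side == "retains_left") "]" else "["
  sprintf("%s:%d%s(%s)", x$chrom, x$pos, arrow, x$strand)
}

#' @export
print.BreakEnd <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Junction feature (breakpoint-junction signature)
#'
#' The mutually exclusive feature taxonomy of a sequenced junction: blunt
#' ends, microhomology of `mh_len` bases, an untemplated insertion, or a
#' templated insertion decomposed into one or more reference loci.
#' Microhomology and inserted sequence never co-occur at a joint.
#'
#' @param kind One of `"blunt"`, `"microhomology"`,
#'   `"untemplated_insertion"`, `"templated_insertion"`.
#' @param mh_len Microhomology length (0 unless kind is microhomology).
#' @param insert_seq Inserted sequence at the joint ("" unless an
#'   insertion kind).
#' @param template_parts For templated insertions, a data.frame with
#'   columns `chrom`, `start`, `end`, `strand`, ordered as the parts occur
#'   in the insert.
#' @param unmatched For partially decomposed inserts, the total length of
#'   sequence not assigned to any template locus.
#' @return An object of class `JunctionFeature`.
#' @export
junction_feature <- function(kind, mh_len = 0L, insert_seq = "",
                             template_parts = NULL, unmatched = 0L) {
  kind <- match.arg(kind, c("blunt", "microhomology",
                            "untemplated_insertion", "templated_insertion"))
  mh_len <- as.integer(mh_len)
  switch(kind,
    blunt = abort_if(mh_len != 0L || nzchar(insert_seq),
                     "blunt feature must have mh_len 0 and empty insert"),
    microhomology = abort_if(mh_len < 1L || nzchar(insert_seq),
                             "microhomology feature needs mh_len >= 1, no insert"),
    untemplated_insertion = abort_if(mh_len != 0L || !nzchar(insert_seq),
                                     "untemplated insertion needs insert, mh_len 0"),
    templated_insertion = {
      abort_if(mh_len != 0L, "templated insertion needs mh_len 0")
      abort_if(is.null(template_parts) || nrow(template_parts) == 0,
               "templated insertion needs template parts")
    }
  )
  if (!is.null(template_parts)) {
    template_parts <- as.data.frame(template_parts)[, c("chrom", "start", "end", "strand")]
    template_parts$start <- as.integer(template_parts$start)
    template_parts$end <- as.integer(template_parts$end)
  }
  structure(list(kind = kind, mh_len = mh_len, insert_seq = insert_seq,
                 template_parts = template_parts,
                 unmatched = as.integer(unmatched)),
            class = "JunctionFeature")
}

#' @export
format.JunctionFeature <- function(x, ...) {
  switch(x$kind,
    blunt = "blunt ends",
    microhomology = sprintf("%dbp MH", x$mh_len),
    untemplated_insertion = sprintf("%dbp insertion", nchar(x$insert_seq)),
    templated_insertion = {
      len <- sum(interval_length(x$template_parts$start, x$template_parts$end)) +
        x$unmatched
      sprintf("%dbp templated insertion (%d part%s)", len,
              nrow(x$template_parts), if (nrow(x$template_parts) > 1) "s" else "")
    })
}

#' @export
print.JunctionFeature <- function(x, ...) {
  cat(format(x), "\n")
  if (!is.null(x$template_parts)) {
    for (i in seq_len(nrow(x$template_parts))) {
      p <- x$template_parts[i, ]
      cat(sprintf("  part %d: %s:%d-%d(%s)\n", i, p$chrom, p$start, p$end, p$strand))
    }
  }
  invisible(x)
}

# total inserted bases implied by a feature
feature_insert_len <- function(f) {
  if (is.null(f)) return(0L)
  if (f$kind == "untemplated_insertion") return(nchar(f$insert_seq))
  if (f$kind == "templated_insertion") {
    return(sum(interval_length(f$template_parts$start, f$template_parts$end)) +
             f$unmatched)
  }
  0L
}

#' Breakpoint junction
#'
#' An oriented breakend pair with optional junction-spanning sequence and
#' feature annotation. Hypothetical junctions (inferred to complete a
#' parsimonious derivative model, flagged `??` in case reports) carry
#' neither a read nor a feature.
#'
#' @param id Junction label.
#' @param a,b [breakend()]s.
#' @param read_seq Junction-spanning sequence, or `NULL`.
#' @param support `"sequenced"` or `"hypothetical"`.
#' @param feature A [junction_feature()], or `NULL` (mandatory `NULL` for
#'   hypothetical junctions; `NULL` with `unresolved = TRUE` for sequenced
#'   junctions that could not be uniquely placed).
#' @param unresolved Logical flag for sequenced-but-unmappable junctions
#'   (e.g. anchors falling in a low copy repeat).
#' @return An object of class `Junction`.
#' @export
junction <- function(id, a, b, read_seq = NULL, support = "sequenced",
                     feature = NULL, unresolved = FALSE) {
  support <- match.arg(support, c("sequenced", "hypothetical"))
  if (support == "hypothetical") {
    abort_if(!is.null(read_seq) || !is.null(feature),
             "hypothetical junctions carry no read and no feature")
  }
  structure(list(id = id, a = a, b = b, read_seq = read_seq,
                 support = support, feature = feature,
                 unresolved = isTRUE(unresolved)),
            class = "Junction")
}

#' @export
format.Junction <- function(x, ...) {
  feat <- if (x$support == "hypothetical") {
    "?? (hypothetical)"
  } else if (x$unresolved) {
    "unresolved"
  } else if (is.null(x$feature)) {
    "unannotated"
  } else {
    format(x$feature)
  }
  sprintf("%s: %s -- %s  [%s]", x$id, format(x$a), format(x$b), feat)
}

#' @export
print.Junction <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

breakend_key <- function(be) sprintf("%s:%d:%s", be$chrom, be$pos, be$side)

#' Compare two junctions up to read orientation
#'
#' Two junctions are the same adjacency when their breakend sets agree on
#' chromosome, position and retained side (strand flips when a junction is
#' read from the opposite derivative orientation, so strand is not
#' compared), and their features agree up to reverse complement of the
#' inserted sequence and reversal of the template part order.
#'
#' @param x,y [junction()]s.
#' @param compare_feature Also require feature agreement.
#' @return `TRUE` or `FALSE`.
#' @export
same_junction <- function(x, y, compare_feature = TRUE) {
  kx <- sort(c(breakend_key(x$a), breakend_key(x$b)))
  ky <- sort(c(breakend_key(y$a), breakend_key(y$b)))
  if (!identical(kx, ky)) return(FALSE)
  if (!compare_feature) return(TRUE)
  fx <- x$feature
  fy <- y$feature
  if (is.null(fx) || is.null(fy)) return(is.null(fx) && is.null(fy))
  if (fx$kind != fy$kind || fx$mh_len != fy$mh_len) return(FALSE)
  if (fx$kind == "untemplated_insertion") {
    return(fx$insert_seq == fy$insert_seq || fx$insert_seq == revcomp(fy$insert_seq))
  }
  if (fx$kind == "templated_insertion") {
    px <- fx$template_parts
    py <- fy$template_parts
    if (nrow(px) != nrow(py)) return(FALSE)
    fwd <- all(px$chrom == py$chrom & px$start == py$start & px$end == py$end &
                 px$strand == py$strand)
    pyr <- py[rev(seq_len(nrow(py))), ]
    flip <- c("+" = "-", "-" = "+")
    rev_ok <- all(px$chrom == pyr$chrom & px$start == pyr$start &
                    px$end == pyr$end & px$strand == flip[pyr$strand])
    return(fwd || rev_ok)
  }
  TRUE
}

# ---- VCF 4.2 breakend (BND) export / import -------------------------------

bnd_alt <- function(be_here, be_mate, ref_base) {
  mate <- sprintf("%s:%d", be_mate$chrom, be_mate$pos)
  bracket <- if (be_mate$side == "retains_right") {
    sprintf("[%s[", mate)
  } else {
    sprintf("]%s]", mate)
  }
  if (be_here$side == "retains_left") paste0(ref_base, bracket)
  else paste0(bracket, ref_base)
}

#' Write junctions as paired VCF 4.2 BND records
#'
#' Each junction becomes a MATEID-linked record pair with INFO keys
#' `SVTYPE=BND`, `MHLEN`, `INSSEQ`, `TPARTS` (comma-joined
#' `chrom:start-end:strand` locus strings) and `SUPPORT`.
#'
#' @param junctions List of [junction()]s.
#' @param file Output path.
#' @param genome Optional [genome_ref()] with sequences used for REF
#'   bases; `N` is written otherwise.
#' @return `file`, invisibly.
#' @export
write_junction_vcf <- function(junctions, file, genome = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=insmech %s", as.character(utils::packageVersion("insmech"))),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend\">",
    "##INFO=<ID=MHLEN,Number=1,Type=Integer,Description=\"Microhomology length\">",
    "##INFO=<ID=INSSEQ,Number=1,Type=String,Description=\"Untemplated inserted sequence\">",
    "##INFO=<ID=TPARTS,Number=.,Type=String,Description=\"Templated-insertion source loci chrom:start-end:strand\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=String,Description=\"sequenced or hypothetical\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  rows <- character(0)
  for (j in junctions) {
    ends <- list(a = j$a, b = j$b)
    ids <- paste0(j$id, c("_bnd1", "_bnd2"))
    for (k in 1:2) {
      here <- ends[[k]]
      mate <- ends[[3 - k]]
      ref_base <- if (!is.null(genome) && has_sequence(genome)) {
        genome_base(genome, here$chrom, here$pos)
      } else {
        "N"
      }
      info <- c(sprintf("SVTYPE=BND"), sprintf("MATEID=%s", ids[3 - k]),
                sprintf("SUPPORT=%s", j$support))
      f <- j$feature
      if (!is.null(f)) {
        info <- c(info, sprintf("MHLEN=%d", f$mh_len))
        if (nzchar(f$insert_seq)) info <- c(info, sprintf("INSSEQ=%s", f$insert_seq))
        if (!is.null(f$template_parts)) {
          tp <- f$template_parts
          info <- c(info, sprintf("TPARTS=%s", paste(
            sprintf("%s:%d-%d:%s", tp$chrom, tp$start, tp$end, tp$strand),
            collapse = ",")))
        }
      }
      rows <- c(rows, paste(here$chrom, here$pos, ids[k], ref_base,
                            bnd_alt(here, mate, ref_base), ".", "PASS",
                            paste(info, collapse = ";"), sep = "\t"))
    }
  }
  writeLines(c(header, rows), file)
  invisible(file)
}

parse_info <- function(s) {
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  vals <- lapply(kv, function(p) if (length(p) > 1) p[2] else TRUE)
  stats::setNames(vals, vapply(kv, `[[`, character(1), 1))
}

#' Read paired BND records written by [write_junction_vcf()]
#'
#' @param file VCF path.
#' @return List of [junction()]s.
#' @export
read_junction_vcf <- function(file) {
  lines <- readLines(file)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  recs <- lapply(fields, function(f) {
    info <- parse_info(f[8])
    alt <- f[5]
    # ALT forms: t[c:p[  t]c:p]  [c:p[t  ]c:p]t
    bracket <- if (grepl("[", alt, fixed = TRUE)) "[" else "]"
    side_here <- if (startsWith(alt, "[") || startsWith(alt, "]")) {
      "retains_right"
    } else {
      "retains_left"
    }
    side_mate <- if (bracket == "[") "retains_right" else "retains_left"
    mate <- strsplit(alt, bracket, fixed = TRUE)[[1]][2]
    mp <- strsplit(mate, ":", fixed = TRUE)[[1]]
    list(chrom = f[1], pos = as.integer(f[2]), id = f[3],
         side = side_here, mate_chrom = mp[1], mate_pos = as.integer(mp[2]),
         mate_side = side_mate, info = info)
  })
  ids <- vapply(recs, `[[`, character(1), "id")
  first <- recs[grepl("_bnd1$", ids)]
  lapply(first, function(r) {
    jid <- sub("_bnd1$", "", r$id)
    f <- NULL
    info <- r$info
    if (r$info$SUPPORT == "sequenced" && !is.null(info$MHLEN)) {
      mh <- as.integer(info$MHLEN)
      if (!is.null(info$TPARTS)) {
        parts <- do.call(rbind, lapply(strsplit(info$TPARTS, ",")[[1]], function(p) {
          m <- regmatches(p, regexec("^(.+):([0-9]+)-([0-9]+):([+-])$", p))[[1]]
          data.frame(chrom = m[2], start = as.integer(m[3]),
                     end = as.integer(m[4]), strand = m[5])
        }))
        f <- junction_feature("templated_insertion", template_parts = parts)
      } else if (!is.null(info$INSSEQ)) {
        f <- junction_feature("untemplated_insertion", insert_seq = info$INSSEQ)
      } else if (mh > 0) {
        f <- junction_feature("microhomology", mh_len = mh)
      } else {
        f <- junction_feature("blunt")
      }
    }
    junction(jid,
             breakend(r$chrom, r$pos, r$side),
             breakend(r$mate_chrom, r$mate_pos, r$mate_side),
             support = r$info$SUPPORT,
             feature = f,
             unresolved = r$info$SUPPORT == "sequenced" && is.null(info$MHLEN))
  })
}

#' Tabulate junction features
#'
#' One row per junction, mirroring the columns of a published
#' junction-feature table.
#'
#' @param junctions List of [junction()]s.
#' @return A data.frame with columns `id`, `breakend_a`, `breakend_b`,
#'   `support`, `feature`, `mh_len`, `insert_len`.
#' @export
junction_feature_table <- function(junctions) {
  do.call(rbind, lapply(junctions, function(j) {
    data.frame(
      id = j$id,
      breakend_a = format(j$a),
      breakend_b = format(j$b),
      support = j$support,
      feature = if (j$support == "hypothetical") "??"
                else if (is.null(j$feature)) "unresolved"
                else format(j$feature),
      mh_len = if (is.null(j$feature)) NA_integer_ else j$feature$mh_len,
      insert_len = feature_insert_len(j$feature),
      stringsAsFactors = FALSE
    )
  }))
}
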