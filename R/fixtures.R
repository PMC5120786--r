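# Machine-readable transcriptions of nine resolved complex-insertion
# cases on a toy coordinate system. The fixtures preserve every printed
# junction feature, segment order, orientation and CNV pattern; Mb-scale
# printed sizes are scaled 100x down, kb-scale sizes and exact printed
# base-pair values (815, 8,192, 5,167, the chr9:5874574-5875388 interval)
# are preserved verbatim. Genomes are coordinate-only: junction features
# are transcribed, not recomputed from sequence.

fixture_dir <- function() {
  system.file("extdata", "cases", package = "insmech")
}

#' List available case fixtures
#'
#' @return Character vector of case ids.
#' @export
list_case_fixtures <- function() {
  sub("\\.yaml$", "", list.files(fixture_dir(), pattern = "\\.yaml$"))
}

yaml_feature <- function(x) {
  if (is.null(x)) return(NULL)
  kind <- x$kind
  if (kind == "templated_insertion") {
    parts <- do.call(rbind, lapply(x$parts, function(p) {
      data.frame(chrom = p$chrom, start = p$start, end = p$end,
                 strand = p$strand)
    }))
    f <- junction_feature("templated_insertion", template_parts = parts)
    if (!is.null(x$printed_total)) {
      attr(f, "printed_total") <- as.integer(x$printed_total)
      attr(f, "printed_total_discrepant") <-
        as.integer(x$printed_total) != feature_insert_len(f)
    }
    f
  } else if (kind == "microhomology") {
    junction_feature("microhomology", mh_len = x$mh_len)
  } else if (kind == "untemplated_insertion") {
    junction_feature("untemplated_insertion", insert_seq = x$insert_seq)
  } else {
    junction_feature("blunt")
  }
}

yaml_junction <- function(x) {
  j <- junction(
    id = x$id,
    a = if (!is.null(x$a)) breakend(x$a$chrom, x$a$pos, x$a$side),
    b = if (!is.null(x$b)) breakend(x$b$chrom, x$b$pos, x$b$side),
    support = x$support %||% "sequenced",
    feature = if (identical(x$support, "hypothetical")) NULL
              else yaml_feature(x$feature)
  )
  attr(j, "repeat_distal") <- x$repeat_distal %||% "-"
  attr(j, "repeat_proximal") <- x$repeat_proximal %||% "-"
  j
}

yaml_calls <- function(x, genome) {
  if (is.null(x) || length(x) == 0) {
    return(cnv_calls(data.frame(chrom = character(0), start = integer(0),
                                end = integer(0), cn = integer(0),
                                baseline = integer(0))))
  }
  calls <- do.call(rbind, lapply(x, function(cc) {
    data.frame(chrom = cc$chrom, start = as.integer(cc$start),
               end = as.integer(cc$end), type = cc$type)
  }))
  calls$baseline <- genome$ploidy[calls$chrom]
  calls$cn <- calls$baseline + c(DEL = -1L, DUP = 1L, TRP = 2L)[calls$type]
  calls$size_bp <- interval_length(calls$start, calls$end)
  calls[, c("chrom", "start", "end", "type", "cn", "baseline", "size_bp")]
}

yaml_walk <- function(x) {
  do.call(rbind, lapply(x, function(s) {
    data.frame(chrom = s$chrom, start = as.integer(s$start),
               end = as.integer(s$end), strand = s$strand)
  }))
}

validate_fixture <- function(fx) {
  g <- fx$genome
  check_interval <- function(chrom, start, end, what) {
    abort_if(!chrom %in% names(g$lengths), "%s: unknown chromosome %s",
             fx$case_id, chrom)
    abort_if(start < 1 || end > g$lengths[[chrom]] || end < start,
             "%s: %s outside chromosome %s", fx$case_id, what, chrom)
  }
  if (nrow(fx$calls)) {
    for (i in seq_len(nrow(fx$calls))) {
      check_interval(fx$calls$chrom[i], fx$calls$start[i], fx$calls$end[i],
                     "CNV call")
    }
    # calls must not overlap within a chromosome
    for (chrom in unique(fx$calls$chrom)) {
      cc <- fx$calls[fx$calls$chrom == chrom, ]
      cc <- cc[order(cc$start), ]
      abort_if(nrow(cc) > 1 && any(cc$start[-1] <= cc$end[-nrow(cc)]),
               "%s: overlapping CNV calls on %s", fx$case_id, chrom)
    }
  }
  for (j in fx$junctions) {
    for (be in list(j$a, j$b)) {
      if (!is.null(be)) check_interval(be$chrom, be$pos, be$pos, "breakend")
    }
    f <- j$feature
    if (!is.null(f) && f$kind == "templated_insertion") {
      for (i in seq_len(nrow(f$template_parts))) {
        p <- f$template_parts[i, ]
        check_interval(p$chrom, p$start, p$end, "template part")
      }
    }
  }
  for (d in fx$parent$derivatives %||% list()) {
    for (i in seq_len(nrow(d$walk))) {
      check_interval(d$walk$chrom[i], d$walk$start[i], d$walk$end[i],
                     "walk segment")
    }
  }
  invisible(fx)
}

#' Load a case fixture
#'
#' @param case_id One of [list_case_fixtures()] (e.g. `"Cplex4"`,
#'   `"PLP1"`, `"Family12"`).
#' @return An object of class `CaseFixture`: genome, CNV calls, junctions,
#'   parent/children sections for family cases, and the case's expected
#'   summary values.
#' @export
load_case_fixture <- function(case_id) {
  path <- file.path(fixture_dir(), paste0(case_id, ".yaml"))
  abort_if(!file.exists(path), "unknown case fixture '%s' (available: %s)",
           case_id, paste(list_case_fixtures(), collapse = ", "))
  y <- yaml::read_yaml(path)
  lengths <- vapply(y$genome$chromosomes, `[[`, numeric(1), "length")
  names(lengths) <- vapply(y$genome$chromosomes, `[[`, character(1), "name")
  ploidy <- vapply(y$genome$chromosomes, function(x) x$ploidy %||% 2L, numeric(1))
  names(ploidy) <- names(lengths)
  genome <- genome_ref(lengths = lengths, ploidy = ploidy)
  fx <- list(
    case_id = y$case_id,
    kind = y$kind,
    insertion_type = y$insertion_type,
    genome = genome,
    recipient = y$recipient,
    calls = yaml_calls(y$calls %||% y$parent$calls, genome),
    junctions = lapply(y$junctions, yaml_junction),
    metadata = y$metadata %||% list(),
    expected = y$expected
  )
  if (identical(y$kind, "family")) {
    fx$parent <- list(
      id = y$parent$id,
      derivatives = lapply(y$parent$derivatives, function(d) {
        list(recipient = d$recipient, walk = yaml_walk(d$walk))
      }),
      calls = yaml_calls(y$parent$calls, genome)
    )
    fx$children <- lapply(y$children, function(ch) {
      cb <- genome$ploidy
      if (!is.null(ch$child_baseline)) {
        for (nm in names(ch$child_baseline)) cb[[nm]] <- ch$child_baseline[[nm]]
      }
      list(id = ch$id, affected = isTRUE(ch$affected),
           child_baseline = cb,
           transmitted = unlist(ch$transmitted),
           calls = yaml_calls(ch$calls, genome))
    })
  }
  structure(validate_fixture(fx), class = "CaseFixture")
}

#' @export
print.CaseFixture <- function(x, ...) {
  cat(sprintf("CaseFixture %s (%s): %d CNV call(s), %d junction(s)\n",
              x$case_id, x$kind, nrow(x$calls), length(x$junctions)))
  invisible(x)
}

sequenced_junctions <- function(fx) {
  Filter(function(j) j$support == "sequenced", fx$junctions)
}

#' Run the full pipeline on a case fixture
#'
#' For rearrangement cases: per-chromosome pattern strings,
#' DUP-TRP/INV-DUP detection, breakpoint-graph reconstruction with
#' hypothetical-junction inference, and mechanism classification. For
#' family cases: transmission-outcome enumeration (independent
#' segregation or single crossover), child matching, and classification
#' of the parental event.
#'
#' @param case_id A case id or a loaded `CaseFixture`.
#' @param ... Passed to [reconstruct()] for rearrangement cases.
#' @return An object of class `CaseReport`.
#' @export
run_case <- function(case_id, ...) {
  fx <- if (inherits(case_id, "CaseFixture")) case_id
        else load_case_fixture(case_id)
  report <- list(case_id = fx$case_id, kind = fx$kind, fixture = fx)
  report$patterns <- stats::setNames(
    lapply(names(fx$genome$lengths), pattern_string, calls = fx$calls),
    names(fx$genome$lengths))
  if (identical(fx$kind, "rearrangement")) {
    graph <- build_graph(fx$calls, sequenced_junctions(fx), fx$genome,
                         recipient = fx$recipient)
    recon <- reconstruct(graph, ...)
    report$graph <- graph
    report$reconstruction <- recon
    model <- if (length(recon$models)) recon$models[[1]] else NULL
    report$model <- model
    if (!is.null(model)) {
      report$n_junctions_total <- count_junctions(model)
      report$n_junctions_sequenced <- count_junctions(model, "sequenced")
      report$n_hypothetical <- count_junctions(model, "hypothetical")
    }
    all_j <- sequenced_junctions(fx)
    if (!is.null(model)) {
      all_j <- c(all_j, Filter(function(j) j$support == "hypothetical",
                               model$junctions_used))
    }
    report$dup_trp_inv_dup <- stats::setNames(
      lapply(unique(fx$calls$chrom), function(chrom) {
        detect_dup_trp_inv_dup(fx$calls[fx$calls$chrom == chrom, , drop = FALSE],
                               all_j)
      }), unique(fx$calls$chrom))
    report$features <- extract_features(model, fx$calls,
                                        sequenced_junctions(fx), fx$metadata)
    report$mechanism <- classify_mechanism(report$features)
  } else {
    parent <- parental_genotype(fx$parent$derivatives, fx$insertion_type)
    report$features <- extract_features(NULL, fx$parent$calls,
                                        sequenced_junctions(fx), fx$metadata)
    report$mechanism <- classify_mechanism(report$features)
    report$children <- lapply(fx$children, function(ch) {
      outcomes <- if (fx$insertion_type == "interchromosomal") {
        enumerate_segregation(parent, fx$genome,
                              child_baseline = ch$child_baseline)
      } else {
        enumerate_crossovers(parent, fx$genome,
                             child_baseline = ch$child_baseline)
      }
      m <- match_child(ch$calls, outcomes)
      list(id = ch$id, outcomes = outcomes, match = m,
           best_outcome = outcomes[[m$best]])
    })
    names(report$children) <- vapply(fx$children, `[[`, character(1), "id")
  }
  structure(report, class = "CaseReport")
}

#' @export
print.CaseReport <- function(x, ...) {
  cat(sprintf("== Case %s (%s) ==\n", x$case_id, x$kind))
  for (chrom in names(x$patterns)) {
    cat(sprintf("  %s pattern: %s\n", chrom, x$patterns[[chrom]]))
  }
  if (identical(x$kind, "rearrangement")) {
    if (!is.null(x$model)) {
      cat(sprintf("  reconstruction: %d junction(s), %d sequenced, %d hypothetical\n",
                  x$n_junctions_total, x$n_junctions_sequenced,
                  x$n_hypothetical))
      cat(derivative_narration(x$model), sep = "\n")
    } else {
      cat("  reconstruction:", x$reconstruction$status, "\n")
    }
    for (chrom in names(x$dup_trp_inv_dup)) {
      if (x$dup_trp_inv_dup[[chrom]]$detected) {
        cat(sprintf("  DUP-TRP/INV-DUP detected on %s\n", chrom))
      }
    }
  } else {
    for (ch in x$children) {
      res <- if (nrow(ch$match$residual) == 0) "no residual CNVs"
             else sprintf("%d residual CNV(s)", nrow(ch$match$residual))
      cat(sprintf("  child %s: best outcome #%d (%s)\n", ch$id, ch$match$best, res))
    }
  }
  cat(sprintf("  mechanism: %s (%s)\n", x$mechanism$label,
              x$mechanism$proposed_repair))
  invisible(x)
}
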