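# Derivative-chromosome reconstruction: split the involved chromosomes at
# every breakend and copy-number boundary, assign each segment the number
# of times the derivative must traverse it, and search exhaustively for a
# telomere-to-telomere walk of the recipient chromosome that uses every
# sequenced junction exactly once. When no walk exists, the minimal set of
# hypothetical junctions completing one is inferred (the case-report '??'
# junctions).
#
# One homolog of each chromosome is assumed intact (constitutional
# heterozygous events): the recipient chromosome contributes baseline - 1
# intact copies, donor chromosomes their full baseline, so a segment's
# derivative multiplicity is its total copy number minus its intact count,
# floored at zero.

normalize_calls <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), cn = integer(0), baseline = integer(0)))
  }
  calls <- as.data.frame(calls)
  if (!"cn" %in% names(calls)) {
    abort_if(!"type" %in% names(calls), "calls need a cn or type column")
    if (!"baseline" %in% names(calls)) calls$baseline <- 2L
    delta <- c(DEL = -1L, DUP = 1L, TRP = 2L)[calls$type]
    calls$cn <- calls$baseline + delta
  }
  if (!"baseline" %in% names(calls)) calls$baseline <- 2L
  calls[, c("chrom", "start", "end", "cn", "baseline")]
}

#' Build a breakpoint graph
#'
#' Splits every involved chromosome at each junction breakend and each
#' copy-number boundary (the common refinement), and assigns every segment
#' its required number of derivative traversals.
#'
#' @param calls Copy-number calls: a `SegmentCN` data.frame (`cn` column)
#'   or `CNVCall` data.frame (`type` column); segments not covered by a
#'   call sit at baseline.
#' @param junctions List of [junction()]s (sequenced; unresolved junctions
#'   without placed breakends are noted but excluded from the walk
#'   constraints).
#' @param genome A [genome_ref()] (sequence optional).
#' @param recipient Recipient chromosome; default: the chromosome carrying
#'   a deletion call, else the first call's chromosome.
#' @return An object of class `BreakpointGraph`.
#' @export
build_graph <- function(calls, junctions, genome, recipient = NULL) {
  calls <- normalize_calls(calls)
  placed <- Filter(function(j) !is.null(j$a) && !is.null(j$b), junctions)
  unplaced <- Filter(function(j) is.null(j$a) || is.null(j$b), junctions)
  chroms <- unique(c(calls$chrom,
                     unlist(lapply(placed, function(j) c(j$a$chrom, j$b$chrom))),
                     recipient))
  chroms <- chroms[chroms %in% names(genome$lengths)]
  abort_if(length(chroms) == 0, "no chromosomes to build a graph on")
  if (is.null(recipient)) {
    del <- calls[calls$cn < calls$baseline, ]
    recipient <- if (nrow(del)) del$chrom[1] else calls$chrom[1]
  }
  abort_if(!recipient %in% names(genome$lengths), "unknown recipient chromosome")
  if (!recipient %in% chroms) chroms <- c(chroms, recipient)

  segs <- list()
  for (chrom in chroms) {
    L <- genome$lengths[[chrom]]
    cuts <- c(0L, L)
    cc <- calls[calls$chrom == chrom, ]
    if (nrow(cc)) cuts <- c(cuts, cc$start - 1L, cc$end)
    for (j in placed) {
      for (be in list(j$a, j$b)) {
        if (be$chrom != chrom) next
        abort_if(be$pos < 1 || be$pos > L,
                 "junction %s breakend outside chromosome %s", j$id, chrom)
        cuts <- c(cuts, if (be$side == "retains_left") be$pos else be$pos - 1L)
      }
    }
    cuts <- sort(unique(pmin(pmax(cuts, 0L), L)))
    starts <- cuts[-length(cuts)] + 1L
    ends <- cuts[-1]
    baseline <- genome$ploidy[[chrom]]
    intact <- baseline - as.integer(chrom == recipient)
    cn <- rep(baseline, length(starts))
    if (nrow(cc)) {
      for (i in seq_len(nrow(cc))) {
        inside <- starts >= cc$start[i] & ends <= cc$end[i]
        cn[inside] <- cc$cn[i]
      }
    }
    segs[[chrom]] <- data.frame(chrom = chrom, start = starts, end = ends,
                                mult = pmax(cn - intact, 0L), cn = cn,
                                baseline = baseline)
  }
  segments <- do.call(rbind, segs)
  segments$id <- seq_len(nrow(segments))
  rownames(segments) <- NULL

  ext_of <- function(be) {
    if (be$side == "retains_left") {
      i <- which(segments$chrom == be$chrom & segments$end == be$pos)
      side <- "R"
    } else {
      i <- which(segments$chrom == be$chrom & segments$start == be$pos)
      side <- "L"
    }
    abort_if(length(i) != 1,
             "breakend %s does not sit at a segment boundary", format(be))
    c(seg = i, side = side)
  }
  adj <- lapply(placed, function(j) {
    list(id = j$id, junction = j,
         ea = ext_of(j$a), eb = ext_of(j$b))
  })
  structure(list(segments = segments, adjacencies = adj,
                 unplaced = unplaced, recipient = recipient, genome = genome),
            class = "BreakpointGraph")
}

#' @export
print.BreakpointGraph <- function(x, ...) {
  cat(sprintf("BreakpointGraph: %d segments on %s; %d novel adjacenc%s; recipient %s\n",
              nrow(x$segments), paste(unique(x$segments$chrom), collapse = ","),
              length(x$adjacencies),
              if (length(x$adjacencies) == 1) "y" else "ies", x$recipient))
  invisible(x)
}

ext_key <- function(e) paste0(e[["seg"]], e[["side"]])

# Depth-first search for telomere-to-telomere walks.
walk_search <- function(graph, extra = list(), max_solutions = 50L) {
  segments <- graph$segments
  n_seg <- nrow(segments)
  adjs <- c(graph$adjacencies, extra)
  n_adj <- length(adjs)
  rec_ids <- which(segments$chrom == graph$recipient & segments$mult >= 1)
  if (length(rec_ids) == 0) return(list())
  start_seg <- min(rec_ids)
  end_seg <- max(rec_ids)

  # adjacency lookup by extremity key
  by_ext <- list()
  for (i in seq_len(n_adj)) {
    for (side in c("ea", "eb")) {
      k <- ext_key(adjs[[i]][[side]])
      by_ext[[k]] <- c(by_ext[[k]], i)
    }
  }
  right_nbr <- integer(n_seg)
  left_nbr <- integer(n_seg)
  for (i in seq_len(n_seg)) {
    r <- which(segments$chrom == segments$chrom[i] &
                 segments$start == segments$end[i] + 1L)
    right_nbr[i] <- if (length(r)) r else NA_integer_
    l <- which(segments$chrom == segments$chrom[i] &
                 segments$end == segments$start[i] - 1L)
    left_nbr[i] <- if (length(l)) l else NA_integer_
  }

  solutions <- list()
  steps <- list()  # rows: seg, orient, via (0 = reference, else adjacency idx), dir
  calls <- 0L

  dfs <- function(cur_seg, cur_orient, mult, used) {
    calls <<- calls + 1L
    if (calls > 2e6 || length(solutions) >= max_solutions) return()
    if (cur_seg == end_seg && cur_orient == "+" &&
        all(mult == 0L) && all(used)) {
      solutions[[length(solutions) + 1]] <<- do.call(rbind, steps)
      return()
    }
    exit_side <- if (cur_orient == "+") "R" else "L"
    # reference adjacency
    nxt <- if (exit_side == "R") right_nbr[cur_seg] else left_nbr[cur_seg]
    if (!is.na(nxt) && mult[nxt] > 0L) {
      mult[nxt] <- mult[nxt] - 1L
      steps[[length(steps) + 1]] <<- data.frame(seg = nxt, orient = cur_orient,
                                                via = 0L, dir = "fwd")
      dfs(nxt, cur_orient, mult, used)
      steps[[length(steps)]] <<- NULL
      mult[nxt] <- mult[nxt] + 1L
    }
    # novel adjacencies incident to the exit extremity
    k <- paste0(cur_seg, exit_side)
    for (ai in by_ext[[k]]) {
      if (used[ai]) next
      a <- adjs[[ai]]
      if (identical(ext_key(a$ea), k)) {
        entry <- a$eb
        dir <- "fwd"
      } else {
        entry <- a$ea
        dir <- "rev"
      }
      eseg <- as.integer(entry[["seg"]])
      if (mult[eseg] <= 0L) next
      orient <- if (entry[["side"]] == "L") "+" else "-"
      used[ai] <- TRUE
      mult[eseg] <- mult[eseg] - 1L
      steps[[length(steps) + 1]] <<- data.frame(seg = eseg, orient = orient,
                                                via = ai, dir = dir)
      dfs(eseg, orient, mult, used)
      steps[[length(steps)]] <<- NULL
      mult[eseg] <- mult[eseg] + 1L
      used[ai] <- FALSE
    }
  }

  mult <- segments$mult
  used <- rep(FALSE, n_adj)
  if (mult[start_seg] <= 0L) return(list())
  mult[start_seg] <- mult[start_seg] - 1L
  steps[[1]] <- data.frame(seg = start_seg, orient = "+", via = 0L, dir = "fwd")
  dfs(start_seg, "+", mult, used)
  solutions
}

hypothetical_candidates <- function(graph) {
  segments <- graph$segments
  active <- which(segments$mult >= 1)
  exts <- unlist(lapply(active, function(i) {
    paste0(i, c("L", "R"))
  }))
  existing <- vapply(graph$adjacencies, function(a) {
    paste(sort(c(ext_key(a$ea), ext_key(a$eb))), collapse = "|")
  }, character(1))
  cands <- list()
  for (i in seq_along(exts)) {
    for (j in seq_along(exts)) {
      if (j <= i) next
      e1 <- exts[i]
      e2 <- exts[j]
      s1 <- as.integer(sub("[LR]$", "", e1))
      s2 <- as.integer(sub("[LR]$", "", e2))
      d1 <- sub("^[0-9]+", "", e1)
      d2 <- sub("^[0-9]+", "", e2)
      # skip reference-adjacent pairs
      if (segments$chrom[s1] == segments$chrom[s2]) {
        if (d1 == "R" && d2 == "L" && segments$start[s2] == segments$end[s1] + 1L) next
        if (d1 == "L" && d2 == "R" && segments$start[s1] == segments$end[s2] + 1L) next
      }
      key <- paste(sort(c(e1, e2)), collapse = "|")
      if (key %in% existing) next
      cands[[length(cands) + 1]] <- list(
        ea = c(seg = s1, side = d1), eb = c(seg = s2, side = d2))
    }
  }
  cands
}

ext_breakend <- function(graph, e) {
  seg <- graph$segments[as.integer(e[["seg"]]), ]
  if (e[["side"]] == "R") breakend(seg$chrom, seg$end, "retains_left")
  else breakend(seg$chrom, seg$start, "retains_right")
}

adjacency_inverted <- function(a) a$ea[["side"]] == a$eb[["side"]]

model_from_solution <- function(graph, sol, adjs) {
  segments <- graph$segments
  walk <- data.frame(chrom = segments$chrom[sol$seg],
                     start = segments$start[sol$seg],
                     end = segments$end[sol$seg],
                     strand = sol$orient)
  junctions_used <- list()
  for (i in seq_len(nrow(sol))) {
    if (sol$via[i] == 0L) next
    a <- adjs[[sol$via[i]]]
    j <- if (!is.null(a$junction)) {
      a$junction
    } else {
      junction(a$id, ext_breakend(graph, a$ea), ext_breakend(graph, a$eb),
               support = "hypothetical")
    }
    attr(j, "after_step") <- i - 1L
    attr(j, "direction") <- sol$dir[i]
    junctions_used[[length(junctions_used) + 1]] <- j
  }
  n_hyp <- sum(vapply(junctions_used, function(j) j$support == "hypothetical",
                      logical(1)))
  structure(list(walk = walk, junctions_used = junctions_used,
                 recipient = graph$recipient, n_hypothetical = n_hyp),
            class = "DerivativeModel")
}

#' @export
print.DerivativeModel <- function(x, ...) {
  cat(sprintf("DerivativeModel der(%s): %d segments, %d junctions (%d hypothetical)\n",
              x$recipient, nrow(x$walk), length(x$junctions_used),
              x$n_hypothetical))
  cat(derivative_narration(x), sep = "\n")
  invisible(x)
}

#' Reconstruct derivative chromosomes from a breakpoint graph
#'
#' Exhaustive search (toy scale) for a telomere-to-telomere walk of the
#' recipient chromosome satisfying every segment multiplicity and using
#' every sequenced junction exactly once. If no such walk exists, the
#' graph is augmented with the minimum number of hypothetical junctions
#' (candidate extremity pairs, searched breadth-first by count) that
#' completes one; ties are broken by fewest inverted hypothetical joins,
#' then lexicographically smallest hypothetical breakend coordinates.
#' All minimal models are returned, ranked.
#'
#' @param graph A [build_graph()] result.
#' @param max_hypothetical Give up after this many hypothetical junctions
#'   (default 3), reporting status `"unreconstructable"`.
#' @param max_models Cap on retained models.
#' @return `list(status, models)` where `models` is a ranked list of
#'   `DerivativeModel`s; `status` is `"ok"` or `"unreconstructable"`.
#' @export
reconstruct <- function(graph, max_hypothetical = 3L, max_models = 20L) {
  top <- function(models) {
    ranked <- rank_models(models)
    ranked[seq_len(min(length(ranked), max_models))]
  }
  sols <- walk_search(graph)
  if (length(sols)) {
    models <- lapply(sols, model_from_solution, graph = graph,
                     adjs = graph$adjacencies)
    return(list(status = "ok", models = top(models)))
  }
  cands <- hypothetical_candidates(graph)
  if (max_hypothetical >= 1) {
    for (k in seq_len(max_hypothetical)) {
      combos <- if (k == 1) {
        lapply(seq_along(cands), function(i) cands[i])
      } else {
        if (length(cands) < k) list() else
          utils::combn(seq_along(cands), k, simplify = FALSE) |>
            lapply(function(ix) cands[ix])
      }
      models <- list()
      for (extra in combos) {
        extra <- lapply(seq_along(extra), function(i) {
          c(extra[[i]], list(id = paste0("H", i), junction = NULL))
        })
        sols <- walk_search(graph, extra = extra, max_solutions = 5L)
        for (s in sols) {
          models[[length(models) + 1]] <-
            model_from_solution(graph, s, c(graph$adjacencies, extra))
        }
        if (length(models) >= 200) break
      }
      if (length(models)) {
        return(list(status = "ok", models = top(models)))
      }
    }
  }
  list(status = "unreconstructable", models = list())
}

rank_models <- function(models) {
  keyf <- function(m) {
    hyp <- Filter(function(j) j$support == "hypothetical", m$junctions_used)
    inv <- sum(vapply(hyp, junction_is_inverted, logical(1)))
    coords <- paste(vapply(hyp, function(j) {
      paste(sort(c(format(j$a), format(j$b))), collapse = "|")
    }, character(1)), collapse = ";")
    walkkey <- paste(m$walk$chrom, m$walk$start, m$walk$strand, collapse = ",")
    list(n_hyp = as.numeric(m$n_hypothetical), inv = as.numeric(inv),
         coords = coords, walk = walkkey)
  }
  keys <- lapply(models, keyf)
  ord <- order(vapply(keys, `[[`, numeric(1), "n_hyp"),
               vapply(keys, `[[`, numeric(1), "inv"),
               vapply(keys, `[[`, character(1), "coords"),
               vapply(keys, `[[`, character(1), "walk"))
  models <- models[ord]
  keys <- keys[ord]
  # drop duplicate walks
  wk <- vapply(keys, function(k) paste(k$walk, k$coords), character(1))
  models[!duplicated(wk)]
}

#' Count junctions in a derivative model
#'
#' @param model A `DerivativeModel`.
#' @param support_filter Optional `"sequenced"` or `"hypothetical"`.
#' @return Integer count.
#' @export
count_junctions <- function(model, support_filter = NULL) {
  js <- model$junctions_used
  if (!is.null(support_filter)) {
    js <- Filter(function(j) j$support == support_filter, js)
  }
  length(js)
}

#' Emit the nucleotide sequence of a derivative model
#'
#' Concatenates the oriented segment sequences, applying each junction's
#' microhomology overlap and junctional insert. Hypothetical junctions
#' contribute an explicit 10-base `N` gap placeholder.
#'
#' @param model A `DerivativeModel` (or a `TruthModel` derivative entry's
#'   walk plus its junction list, via the `walk`/`junctions` arguments).
#' @param genome A [genome_ref()] with sequences.
#' @return Nucleotide string.
#' @export
emit_derivative_sequence <- function(model, genome) {
  require_sequence(genome, "emit_derivative_sequence")
  walk <- model$walk
  jbystep <- list()
  for (j in model$junctions_used) {
    jbystep[[as.character(attr(j, "after_step"))]] <- j
  }
  out <- genome_seq(genome, walk$chrom[1], walk$start[1], walk$end[1],
                    walk$strand[1])
  for (i in seq_len(nrow(walk) - 1)) {
    j <- jbystep[[as.character(i)]]
    m <- 0L
    ins <- ""
    if (!is.null(j)) {
      if (j$support == "hypothetical" || is.null(j$feature)) {
        ins <- strrep("N", 10)
      } else {
        f <- j$feature
        if (f$kind == "microhomology") m <- f$mh_len
        ins <- joint_insert_seq(genome, f)
        if (identical(attr(j, "direction"), "rev") && nzchar(ins)) {
          ins <- revcomp(ins)
        }
      }
    }
    sseq <- genome_seq(genome, walk$chrom[i + 1], walk$start[i + 1],
                       walk$end[i + 1], walk$strand[i + 1])
    out <- paste0(out, ins, substr(sseq, m + 1L, nchar(sseq)))
  }
  out
}

#' Convert a simulated truth derivative into a `DerivativeModel`
#'
#' @param truth A `TruthModel`.
#' @param index Which derivative (default 1).
#' @return A `DerivativeModel` whose walk and ordered junction list mirror
#'   the simulated truth.
#' @export
truth_derivative_model <- function(truth, index = 1L) {
  d <- truth$derivatives[[index]]
  jids <- which(vapply(seq_along(truth$junctions), function(i) {
    k <- 0
    for (di in seq_along(truth$derivatives)) {
      for (m in truth$derivatives[[di]]$joints) {
        k <- k + 1
        if (k == i) return(di == index)
      }
    }
    FALSE
  }, logical(1)))
  junctions_used <- lapply(seq_along(jids), function(i) {
    j <- truth$junctions[[jids[i]]]
    attr(j, "after_step") <- i
    attr(j, "direction") <- "fwd"
    j
  })
  n_hyp <- sum(vapply(junctions_used, function(j) j$support == "hypothetical",
                      logical(1)))
  structure(list(walk = d$walk, junctions_used = junctions_used,
                 recipient = d$recipient, n_hypothetical = n_hyp),
            class = "DerivativeModel")
}

#' Human-readable walk narration
#'
#' A plain-text account of a derivative model in case-report style:
#' ordered oriented segments and the junction joining each consecutive
#' pair.
#'
#' @param model A `DerivativeModel`.
#' @return Character vector of lines.
#' @export
derivative_narration <- function(model) {
  walk <- model$walk
  lines <- sprintf("  %2d. %s:%d-%d (%s)", seq_len(nrow(walk)), walk$chrom,
                   walk$start, walk$end, walk$strand)
  for (j in model$junctions_used) {
    i <- attr(j, "after_step")
    lines[i] <- paste0(lines[i], sprintf("   -> via %s%s", j$id,
                                         if (j$support == "hypothetical") " (??)" else ""))
  }
  lines
}

#' Serialize a derivative model as an ordered segment table
#'
#' @param model A `DerivativeModel`.
#' @param file Optional TSV path.
#' @return Data.frame with the walk and junction ids.
#' @export
derivative_table <- function(model, file = NULL) {
  walk <- model$walk
  walk$junction_after <- ""
  for (j in model$junctions_used) {
    walk$junction_after[attr(j, "after_step")] <-
      paste0(j$id, if (j$support == "hypothetical") "(??)" else "")
  }
  if (!is.null(file)) {
    utils::write.table(walk, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  walk
}
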