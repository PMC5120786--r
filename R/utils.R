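#' Inclusive length of a 1-based, fully-closed genomic interval
#'
#' All coordinates in this package are 1-based and fully closed, the
#' convention used when junction coordinates are reported against
#' GRCh37/hg19. Under that convention the interval chr9:5874574-5875388
#' spans 815 bp.
#'
#' @param start,end Integer vectors of interval boundaries, `end >= start`.
#' @return Integer vector of lengths `end - start + 1`.
#' @export
#' @examples
#' interval_length(5874574, 5875388)  # 815
interval_length <- function(start, end) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(end < start)) stop("interval end precedes start")
  as.integer(end - start + 1)
}

#' Incidence of chromosomal insertions in a screened cohort
#'
#' Expresses a carrier count as a "1 in N individuals tested" rate.
#'
#' @param n_tested Number of individuals screened.
#' @param n_carriers Number of insertion carriers found among them.
#' @return The denominator N of the "1 in N" rate (`n_tested / n_carriers`).
#' @export
#' @examples
#' insertion_incidence(38000, 76)  # 500
insertion_incidence <- function(n_tested, n_carriers) {
  if (n_carriers <= 0) stop("n_carriers must be positive")
  n_tested / n_carriers
}

#' Reverse complement of nucleotide strings
#'
#' @param x Character vector of ACGT strings (may contain empty strings).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (is.na(s) || nchar(s) == 0L) return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

# Evaluate `code` under a fixed RNG seed without disturbing global RNG state.
# Every stochastic operation in the package routes its randomness through
# this helper so a single integer seed per call fixes the output.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (!is.null(old)) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# stopifnot with a formatted message
abort_if <- function(cond, fmt, ...) {
  if (isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(NULL)
}
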