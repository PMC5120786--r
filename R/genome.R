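#' Reference genome container
#'
#' A `GenomeRef` holds named chromosome sequences (optional) together with
#' chromosome lengths and a per-chromosome ploidy baseline (2 for
#' autosomes, 1 or 2 for the X depending on sex). Coordinates are 1-based
#' and fully closed throughout.
#'
#' Coordinate-only genomes (lengths but no sequence) are supported for
#' case fixtures whose junction features are transcribed rather than
#' recomputed; operations that need nucleotide content reject them with an
#' explicit error.
#'
#' @param sequences Named character vector of uppercase ACGT chromosome
#'   sequences, or `NULL` for a coordinate-only genome.
#' @param lengths Named integer vector of chromosome lengths; derived from
#'   `sequences` when those are given.
#' @param ploidy Named integer vector of baseline copy numbers; defaults
#'   to 2 for every chromosome.
#' @return An object of class `GenomeRef`.
#' @export
genome_ref <- function(sequences = NULL, lengths = NULL, ploidy = NULL) {
  if (is.null(sequences) && is.null(lengths)) {
    stop("supply sequences or lengths")
  }
  if (!is.null(sequences)) {
    abort_if(is.null(names(sequences)) || anyDuplicated(names(sequences)) > 0,
             "chromosome names must be present and unique")
    bad <- grepl("[^ACGT]", sequences)
    abort_if(any(bad), "chromosome %s contains non-ACGT characters",
             names(sequences)[bad][1])
    lengths <- stats::setNames(nchar(sequences), names(sequences))
  } else {
    abort_if(is.null(names(lengths)) || anyDuplicated(names(lengths)) > 0,
             "chromosome names must be present and unique")
    lengths <- stats::setNames(as.integer(lengths), names(lengths))
  }
  abort_if(any(lengths < 1L), "non-positive chromosome length")
  if (is.null(ploidy)) {
    ploidy <- stats::setNames(rep(2L, length(lengths)), names(lengths))
  } else {
    abort_if(!all(names(lengths) %in% names(ploidy)),
             "ploidy must cover every chromosome")
    ploidy <- stats::setNames(as.integer(ploidy[names(lengths)]), names(lengths))
  }
  structure(
    list(sequences = sequences, lengths = lengths, ploidy = ploidy),
    class = "GenomeRef"
  )
}

#' @export
print.GenomeRef <- function(x, ...) {
  cat(sprintf("GenomeRef: %d chromosome(s)%s\n", length(x$lengths),
              if (is.null(x$sequences)) " (coordinate-only)" else ""))
  for (nm in names(x$lengths)) {
    cat(sprintf("  %s  %s bp  ploidy %d\n", nm,
                format(x$lengths[[nm]], big.mark = ","), x$ploidy[[nm]]))
  }
  invisible(x)
}

has_sequence <- function(genome) !is.null(genome$sequences)

require_sequence <- function(genome, what) {
  abort_if(!has_sequence(genome),
           "%s requires a genome with sequences (coordinate-only GenomeRef given)",
           what)
}

#' Generate a random toy genome
#'
#' Draws i.i.d. bases at a target GC fraction. The result is deterministic
#' for a given seed: the same call always yields byte-identical sequences.
#' Lengths are restricted to desk scale (1 kb to 10 Mb per chromosome).
#'
#' @param n_chroms Number of chromosomes (1 to 5).
#' @param lengths Integer vector of chromosome lengths, recycled to
#'   `n_chroms`.
#' @param gc Target GC fraction in (0, 1).
#' @param seed Integer seed fixing the sequences.
#' @param chrom_names Optional chromosome names (default `chr1`, ...).
#' @param ploidy Optional named ploidy vector (default all 2).
#' @return A [genome_ref()] with sequences.
#' @export
make_toy_genome <- function(n_chroms, lengths, gc = 0.41, seed,
                            chrom_names = NULL, ploidy = NULL) {
  abort_if(n_chroms < 1 || n_chroms > 5, "n_chroms must be in 1..5")
  lengths <- as.integer(rep_len(as.numeric(lengths), n_chroms))
  abort_if(any(lengths <= 0), "non-positive chromosome length")
  abort_if(any(lengths < 1000L) || any(lengths > 10e6),
           "chromosome lengths must lie in [1 kb, 10 Mb]")
  abort_if(gc <= 0 || gc >= 1, "gc must be a fraction in (0, 1)")
  if (is.null(chrom_names)) chrom_names <- paste0("chr", seq_len(n_chroms))
  abort_if(anyDuplicated(chrom_names) > 0, "chromosome names must be unique")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- with_seed(seed, {
    vapply(lengths, function(L) {
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
    }, character(1))
  })
  names(seqs) <- chrom_names
  genome_ref(sequences = seqs, ploidy = ploidy)
}

#' Extract genomic sequence
#'
#' @param genome A [genome_ref()] with sequences.
#' @param chrom Chromosome name.
#' @param start,end 1-based closed interval.
#' @param strand `"+"` for the reference strand, `"-"` for its reverse
#'   complement.
#' @return A nucleotide string.
#' @export
genome_seq <- function(genome, chrom, start, end, strand = "+") {
  require_sequence(genome, "genome_seq")
  abort_if(!chrom %in% names(genome$lengths), "unknown chromosome '%s'", chrom)
  L <- genome$lengths[[chrom]]
  abort_if(start < 1 || end > L || end < start,
           "interval %s:%d-%d outside chromosome (length %d)",
           chrom, start, end, L)
  s <- substr(genome$sequences[[chrom]], start, end)
  if (strand == "-") s <- revcomp(s) else abort_if(strand != "+", "bad strand")
  s
}

# Single base at pos on the + strand, or NA when pos is off-chromosome.
genome_base <- function(genome, chrom, pos) {
  if (pos < 1 || pos > genome$lengths[[chrom]]) return(NA_character_)
  substr(genome$sequences[[chrom]], pos, pos)
}

# Overwrite genome bases (used by the microhomology-engineering step of the
# simulator, which adjusts the toy reference at genome-construction time so
# requested junction features are exactly realizable).
genome_write <- function(genome, chrom, pos, bases) {
  require_sequence(genome, "genome_write")
  n <- nchar(bases)
  abort_if(pos < 1 || pos + n - 1 > genome$lengths[[chrom]],
           "write outside chromosome %s", chrom)
  s <- genome$sequences[[chrom]]
  substr(s, pos, pos + n - 1) <- bases
  genome$sequences[[chrom]] <- s
  genome
}

# A base different from every base in `avoid`.
other_base <- function(avoid) {
  setdiff(c("A", "C", "G", "T"), avoid)[1]
}

#' Write a genome (or any named sequence set) to FASTA
#'
#' @param genome A [genome_ref()] with sequences, or a named character
#'   vector of sequences.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_fasta <- function(genome, file) {
  seqs <- if (inherits(genome, "GenomeRef")) {
    require_sequence(genome, "write_fasta")
    genome$sequences
  } else {
    genome
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), filepath = file)
  invisible(file)
}

#' Read a FASTA file into a named character vector
#'
#' @param file FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  stats::setNames(as.character(x), names(x))
}
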