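# insmech

Complex chromosomal insertions — segments of one chromosome translocated
into a non-homologous chromosome or a non-adjacent locus — require at
least three DNA breakage-and-joining events, and the clinically observed
ones are often far more complex: extra duplications and triplications at
the donor and acceptor loci, junctions stitched together from templated
copies of distant sequence, and "balanced" parental insertions that turn
out to harbour small flanking copy-number variants (CNVs). `insmech`
implements, as a tested pipeline, the chain of inference used to resolve
such cases from clinical array-CGH and breakpoint-sequencing data:

* **Junction annotation** — given a junction-spanning sequence and a
  reference, locate the two breakends by maximal exact anchors and derive
  the standard feature taxonomy: blunt ends, microhomology (MH) of *k*
  bp, untemplated insertions, or templated insertions decomposed into
  their source loci.
* **Copy-number patterns** — segment probe-level log2(test/reference)
  ratios into integer copy-number states, express each chromosome as a
  pattern string (e.g. `DUP-NML-DEL-NML-DEL`), and recognize
  DUP-TRP/INV-DUP: a triplication embedded, inverted, within a
  duplication.
* **Derivative reconstruction** — split the involved chromosomes at every
  breakend and CNV boundary, give each segment a required number of
  derivative traversals (copy number minus intact homologs), and search
  exhaustively for a telomere-to-telomere walk using every sequenced
  junction exactly once. When no walk exists, the minimal set of
  *hypothetical* junctions (the `??` junctions of case reports) that
  completes one is inferred.
* **Mechanism classification** — an evidence-trailed rule cascade
  separating *basic complex insertions* (one duplication inserted into a
  deletion; blunt/short-MH junctions; NHEJ, MMEJ or a single template
  switch) from *chromoanasynthesis* (multiple gains including
  triplications, MH > 4 bp, long multi-locus templated insertions;
  iterative FoSTeS/MMBIR template switching) and *balanced end-joining
  exchanges*.
* **Inheritance modelling** — for a carrier parent, enumerate meiotic
  outcomes: independent segregation of interchromosomal derivatives
  (2^k combinations) or single crossovers between an intrachromosomal
  derivative and the intact homolog, predicting each child's CNV profile
  and matching observed children against them.
* **Simulation** — a seeded generator of replicative template-switch
  chains and end-joining exchanges that emulates the assays the pipeline
  consumes (probe tables, junction-spanning reads) with exact ground
  truth, used throughout the test suite as an oracle.

Nine resolved clinical cases ship as toy-coordinate fixtures
(`inst/extdata/cases/`), preserving every printed junction feature,
segment order, orientation, CNV pattern and repeat-element label.

## A worked example

Simulate a two-switch replicative chain — a donor fragment of chr2 copied
into a deleted interval of chr1, with 3 bp of microhomology at the first
joint — then recover everything from the emulated assays:

```r
library(insmech)

g <- make_toy_genome(2, c(60000, 50000), gc = 0.41, seed = 11)
chain <- event_chain(
  start  = list(chrom = "chr1", pos = 20000),
  events = list(
    switch_event("chr2", 10000, "direct", mh_len = 3, seg_len = 800),
    switch_event("chr1", 21500, "direct")
  ),
  resolution = list(chrom = "chr1", pos = 21500), seed = 1)
truth <- simulate_replicative(g, chain)
truth
#> TruthModel: 1 derivative(s), 2 junction(s)
#>   der(chr1): 3 segments, 59,298 bp
#>   2 non-baseline copy-number segment(s)

junction_feature_table(truth$junctions)
#>   id     breakend_a     breakend_b   support    feature mh_len insert_len
#> 1 J1 chr1:20000](+) chr2:10000[(+) sequenced     3bp MH      3          0
#> 2 J2 chr2:10799](+) chr1:21500[(+) sequenced blunt ends      0          0
```

The truth CNV profile shows the expected donor duplication (copy number
3 over 800 bp of chr2) and acceptor deletion (copy number 1 over
chr1:20001-21499). Annotating the emulated junction reads recovers the
features exactly, and reconstruction rebuilds the derivative walk from
calls and junctions alone:

```r
reads <- emit_junction_reads(truth, flank_bp = 500)
annotate_junctions(reads, truth$genome)[["J1"]]
#> J1: chr1:20000](+) -- chr2:10000[(+)  [3bp MH]

graph <- build_graph(truth$truth_cnv, truth$junctions, truth$genome,
                     recipient = "chr1")
reconstruct(graph)$models[[1]]
#> DerivativeModel der(chr1): 3 segments, 2 junctions (0 hypothetical)
#>    1. chr1:1-20000 (+)   -> via J1
#>    2. chr2:10000-10799 (+)   -> via J2
#>    3. chr1:21500-60000 (+)
```

Running a transcribed clinical case end to end — here the most complex
fixture, a rearranged chr13 with multiple inserted chrX fragments and a
templated insertion revealing a third chromosome:

```r
run_case("Cplex11")
#> == Case Cplex11 (rearrangement) ==
#>   chr13 pattern: DUP-NML-DUP-NML-DEL
#>   chrX pattern: DUP-NML-DUP-TRP-DUP
#>   chr4 pattern: NML
#>   reconstruction: 6 junction(s), 5 sequenced, 1 hypothetical
#>   ...
#>   DUP-TRP/INV-DUP detected on chrX
#>   mechanism: chromoanasynthesis (FoSTeS/MMBIR-iterative)
```

The reconstruction uses the five sequenced junctions and infers the one
hypothetical junction needed to complete a copy-number-consistent
derivative — six junctions in total, with the embedded chrX triplication
traversed twice in inverted orientation.

A thin command-line front end (`inst/cli/cgr`) exposes the same stages as
subcommands (`simulate`, `annotate`, `call-cnv`, `reconstruct`,
`classify`, `family`, `run-case`), e.g.
`inst/cli/cgr run-case Cplex4`.

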