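---
title: "Resolving complex chromosomal insertions: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving complex chromosomal insertions: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insmech)
```

# The inference problem

A complex chromosomal insertion presents clinically as a copy-number gain
that FISH shows to be sitting somewhere it does not belong, usually with
additional gains or losses at the donor and acceptor loci. Three data
layers are available: probe-level array-CGH log2 ratios, the set of
breakpoint-junction sequences that long-range PCR and Sanger sequencing
managed to cross, and pedigree information. The scientific question is
mechanistic: was the rearrangement stitched together by end joining
(NHEJ/MMEJ), which ligates broken ends and cannot create new copies, or
by replicative repair (FoSTeS/MMBIR), in which a collapsed replication
fork iteratively invades other loci, copying them and leaving
characteristic scars — longer microhomology, and junctional insertions
templated from the invaded loci?

`insmech` encodes that reasoning as a pipeline with explicit,
individually testable stages. This vignette documents the models behind
each stage, the parameters that matter, and the design decisions taken
where the methodology was genuinely open.

# Junction annotation

A junction-spanning read is mapped by its two *maximal exact anchors*:
the longest prefix and the longest suffix of the read matching the
reference exactly, on either strand of any chromosome. Anchor matching is
exact because the package targets mutation-free toy references and Sanger
consensus sequences; this keeps the relationship between the simulator
and the annotator provable rather than heuristic. Each anchor must be
unique at its maximal length; a tie (for instance both copies of a low
copy repeat) raises an ambiguity condition, and the junction is recorded
as sequenced-but-unresolved — exactly how unmappable junctions are
carried in case reports.

Three geometries follow. Overlapping anchors mean the joint sequence is
present once in the read but attributable to both flanks: microhomology
of length equal to the overlap, with breakend positions placed at the
*outer* tract boundaries so the shared tract is included in both retained
flanks. Abutting anchors are blunt. A gap between anchors is a junctional
insert, classified by greedy left-to-right decomposition into maximal
exact genome matches:

* `min_template_len` (default **10 bp**) separates "templated" from
  "untemplated": published untemplated inserts at such junctions run
  2–18 bp while templated ones are 7 bp to several kb with identifiable
  sources, so 10 bp is a workable boundary — but it is configurable, and
  on large genomes a 10-mer match is unremarkable, so the threshold
  should scale with genome size (see *Limitations*).
* The **longest match wins**, searched genome-wide; `near_window_bp`
  (default **20 kb**) only breaks ties among equal-length maxima in
  favour of loci near either breakend, then chromosome name, coordinate,
  and `+` strand. An earlier draft searched the near window *before* the
  genome: that ordering lets a spurious short local match shadow the true
  longer source and was discarded — templated insertions at real
  junctions are identified by their best, not their nearest, match.
* A partially decomposed middle is reported as templated with the
  unmatched remainder recorded; remainders of at least `min_template_len`
  additionally raise a mixed-feature warning.

Reads are annotated in both orientations and a deterministic canonical
representation is kept, so annotation is invariant under reverse
complement of the input. Microhomology is defined on the derivative
joint: for inverted joins the flanks are compared after reverse
complementation. Whether published junction tables measured inverted
joins on the derivative or the reference plus strand is generally
unstated; the derivative convention is used here and is self-consistent
with the simulator.

`measure_microhomology()` reports the maximal *k* for which the two
reference flanks share their terminal *k* bases. On homopolymer edges
this flank-sharing value can exceed the anchor overlap a read exhibits
(the tests assert it is never smaller); the read-derived feature from
`annotate_junction()` is the authoritative junction label.

# Copy-number segmentation and patterns

Segmentation is deliberately plain: greedy binary change-point splitting
on the mean log2 ratio, each split accepted when its z statistic against
a robust noise estimate (median absolute successive difference, floored
at 10^-3) exceeds `z_thresh` (default **4**), with at least `min_probes`
(default **5**) probes per segment. Segments are snapped to the nearest
integer copy number using the chromosome's ploidy baseline — supplied by
the genome, never inferred from the data, which matters for male X
chromosomes. Circular binary segmentation or HMMs would be overkill: the
package's scientific content lies downstream of segmentation, and on
200 bp probe spacing (the high-density array design emulated here) the
z-test recovers integer states exactly for CNVs of 20+ probes at
realistic noise (sd 0.15 on the log2 ratio), which the test suite
verifies across seeds. Segment boundaries are placed midway between
flanking probes, so calls carry a positional uncertainty of half the
probe spacing.

Pattern strings (`DUP-NML-DEL-NML-DEL`) list the ordered non-baseline
calls on a chromosome with `NML` interposed across gaps larger than
`gap_tol` (default 0 bp — adjacent calls like a triplication inside a
duplication run stay unseparated). DUP-TRP/INV-DUP detection requires
both the copy-number geometry (a TRP strictly inside a contiguous gain
run with duplicated flanks on both sides) and inversion evidence: at
least one junction whose breakends retain the same flank side
(head-to-head or tail-to-tail) located within `slop_bp` (default 5 bp)
of a TRP or gain-run boundary. The inversion requirement is definitional
— a triplication inside a duplication with all-direct junctions is a
different lesion — and the boundary tolerance is tight because toy
coordinates are exact.

# Derivative reconstruction

The breakpoint graph splits every involved chromosome at each breakend
and CNV boundary (the common refinement). Each segment receives a
multiplicity: the number of times the derivative must traverse it,
computed as total copy number minus the intact copies. One homolog of
each chromosome is assumed intact — all cases modelled here are
heterozygous constitutional events — so the *recipient* chromosome
contributes baseline − 1 intact copies while purely *donor* chromosomes
contribute their full baseline. This role-aware accounting is what makes
a donor duplication a single derivative traversal and an acceptor
deletion zero traversals.

Reconstruction is an exhaustive depth-first search for a
telomere-to-telomere walk of the recipient that consumes every segment
multiplicity and uses every sequenced junction exactly once. Instances
here have at most ~20 segments, well within exhaustive reach; a search
budget caps pathological inputs. If no walk exists, candidate
hypothetical junctions (all extremity pairs of traversable segments,
minus existing adjacencies) are added breadth-first by count up to
`max_hypothetical` (default **3**), so the reported models always carry
the minimum number of inferred junctions. Ties are broken by fewest
inverted hypothetical joins, then lexicographically smallest hypothetical
breakend coordinates. All minimal models are returned, ranked: minimal
models are not always unique — an inserted cassette traversed
forward-then-inverted can sometimes be re-ordered without violating any
junction — and the package reports the set rather than asserting
uniqueness. The test suite requires the true walk to be among the
returned models (verified by derivative-sequence identity), and that
withholding one junction from a simulated case re-derives exactly that
junction as the sole hypothetical one.

Walks are anchored in `+` orientation at both recipient telomeres;
whole-derivative reverse complements are therefore canonicalized away.

# Mechanism classification

The cascade consumes aggregated case features and yields a label with a
complete evidence trail (every rule consulted, with its observed value):

1. **chromoanasynthesis** — multiple gains or a triplication, together
   with a replicative junction signature: microhomology longer than
   `mh_cutoff` (default **4 bp**) or any templated insertion;
2. **chromoanasynthesis**, flagged as outside the observed spectrum —
   any gain co-occurring with a templated insertion (no published case
   combines exactly one gain with a templated insert; the templated
   insert is diagnostic of replication, so such cases route to the
   replicative class with a note);
3. **basic complex insertion** — exactly one gain, no triplication, a
   deletion at the insertion site, microhomology at most `basic_mh_max`
   (default **3 bp**) and no templated insertion;
4. **balanced end-joining exchange** — no copy-number gain and all
   residual CNVs at most `small_cnv_max` (default **10 kb**, covering
   the few-kb flanking deletions such events leave behind). No
   microhomology cap applies here: MMEJ tolerates substantial
   microhomology, and the bidirectional-exchange family modelled in the
   fixtures carries a 6 bp MH junction yet is end-joining by the
   copy-number argument;
5. otherwise **unclassified**.

Blunt junctions never veto a replicative call — replicative CGRs
routinely include blunt or 1–2 bp MH joints — and `de novo` status is
carried as metadata in the evidence but never used by the rules: it is
pedigree information, not molecular signal. One fixture (the
intrachromosomal insertion family) lands in `unclassified`: its mother
shows three small gains but an untemplated 18 bp insert and no long
microhomology, so the sequence-level cascade finds no replicative
signature even though the flanking gains themselves argue for a
replicative origin. The cascade deliberately does not encode
"flanking gains imply replication" as a rule, because it would collapse
category 4 entirely; the case is left honest.

# Inheritance modelling

Interchromosomal carriers segregate each involved chromosome
independently: 2^k outcomes, each scored by rebuilding the child's copy
number as (other parent's reference contribution) + (transmitted
homologs' traversal counts). The child baseline is configurable per
chromosome (1 for the X of a male child), and the second parent is
assumed to contribute reference chromosomes.

Intrachromosomal carriers additionally recombine. A single crossover
between the derivative and the intact homolog is modelled at grid-sampled
positions (`interval_grid_bp`, default **10 kb**) within the unrearranged
interval separating the acceptor site from the donor region — computed
as the largest stretch between consecutive breakends on the recipient,
overridable explicitly. Each position yields the two reciprocal
recombinants, one duplication-bearing and one deletion-bearing; grid
positions inside rearranged material (covered more than once or
traversed inverted) would generate further complexity and are excluded
with a flag. Double crossovers are out of scope; no modelled pedigree
requires them. The reciprocality invariant — the two products' deviations
from baseline sum exactly to the parental imbalance — is asserted in the
tests by segment-count arithmetic.

Observed children are matched to outcomes by summed reciprocal overlap of
same-type calls (minimum **0.5**, with boundary fuzz up to `slop_bp`,
default 1 kb, counting as exact); unexplained observed calls are reported
as residual, which is precisely where a case's "additional complexities"
surface.

# The simulator and what passing tests mean

The simulator generates the study's conditions, not arbitrary ones: toy
genomes of 1 kb–10 Mb per chromosome (defaults: three chromosomes of
60/50/40 kb at GC 0.41), template-switch chains of 1–4 events,
junctional microhomology of 0–20 bp, untemplated inserts of 1–20 bp, and
templated inserts copied from 1–3 loci (25–400 bp per part in the
property suites) on up to three chromosomes; end-joining exchanges use
blunt/1–3 bp MH/1–3 bp insert junctions, optional reciprocal fragments,
and optional flank trimming. Probe emulation places one probe per
`spacing_bp` (default **200 bp**) with i.i.d. Gaussian noise on the log2
ratio.

Microhomology is *constructed*, not sampled post hoc: the simulator
first searches landing sites within ±50 bp of the requested target where
the flanks already share exactly the requested tract, and otherwise
rewrites at most `mh_len + 2` reference bases around the joint before
any sequence is emitted, then re-validates. Guards pin each signature
exactly: anchor-extension checks on both sides of every joint,
regeneration of untemplated inserts that contain any genome-matching
10-mer, and inter-part boundary checks for templated inserts *in both
read orientations* (greedy decomposition of the reverse-complemented
read would otherwise overshoot a part boundary with probability ~1/4 per
boundary). With engineering disabled, an unrealizable joint is an
explicit error naming the joint — never a silent truncation. Blunt is
treated as exact zero-overlap concatenation; whether published "blunt"
calls tolerated mismatched joint bases is unstated, and the stricter
reading is the only one the simulator can guarantee.

What the simulator does *not* emulate bounds what green tests show:
no GC waves or dye bias on the array (only i.i.d. noise), no repeats or
segmental duplications in the toy genomes (anchor ambiguity is tested by
explicit construction instead), no sequencing errors in junction reads,
no mosaicism, and no replication-timing or micronucleus biology. Exact
round-trip recovery on 200 seeded junctions therefore demonstrates
internal consistency of the annotation logic at nucleotide resolution,
not robustness to the alignment artifacts of real genomes.

# Numerical and degenerate-input choices

* Coordinates are 1-based fully closed everywhere internally; BED export
  converts to 0-based half-open, and headers label the convention. The
  inclusive length of an interval is `end - start + 1` (an 815 bp
  fragment spans printed coordinates 5874574–5875388).
* Copy number 0 would put the log2 ratio at −∞; probe emulation floors
  the ratio at 0.05 (deep-loss saturation, ≈ −5.3 against a diploid
  baseline).
* A chromosome with fewer than `min_probes` probes segments to a single
  baseline segment with a warning; an all-baseline table yields an empty
  call set; a junction-free, CNV-free graph reconstructs the reference
  chromosome.
* Fixture coordinates scale Mb-scale printed sizes down 100× to keep
  desk-scale chromosomes; kb-scale printed sizes (a 6 kb triplication in
  a 70 kb duplication; 10/22/182 kb flanking CNVs) and exact printed
  base-pair values (815; 8,192; 5,167; the chr9 interval above) are
  preserved verbatim. One published junction lists a templated-insert
  total two bases short of the sum of its two printed parts; the fixture
  stores the parts and the printed total and flags the discrepancy
  rather than reconciling it.
* All randomness flows from a single integer seed per call through a
  local RNG scope; no function touches the global RNG state.

# Limitations

The pipeline assumes exact sequence identity for anchors and template
matches, heterozygous constitutional events with one intact homolog, at
most one derivative per chromosome per parent, and single meiotic
crossovers. `min_template_len = 10` is appropriate for toy genomes of
tens of kb to a few Mb; on a full mammalian genome it must be raised (or
replaced by a mappability-aware criterion) since random 10-mers recur.
Reconstruction is exhaustive and intended for ≤ ~20 segments; the
hypothetical-junction search grows combinatorially with
`max_hypothetical` and is practical because published cases need at most
one inferred junction. Classification is a deterministic rule cascade
mirroring published criteria, not a calibrated probabilistic model; its
100% agreement with the simulator's generative labels (asserted in the
acceptance tests) is a consistency check on noise-free truth, not a
clinical validation.
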