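---
title: "Methods: simulating and recovering horizontal gene transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and recovering horizontal gene transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgtbench)
```

This vignette explains the models implemented by `hgtbench`, the choices
made where a design was genuinely open, and what the synthetic benchmark
does and does not demonstrate about real data.

## The codon mutation model

Transferred genes diverge from their donor copies over time. To emulate
that divergence without frameshifts, the unit of mutation is the codon,
and each mutation event belongs to one of four categories: C1 (one base,
silent), C2 (one base, non-silent), C3 (two bases, any effect), C4 (three
bases, any effect). The base cost per event is (1, 1, 2, 3).

Start codons and stop codons are excluded from the mutation space as both
sources and targets, so no event can destroy a start, read through a stop,
or create an internal stop. Two choices deserve comment:

* **The excluded set.** We exclude the bacterial-style start set
  {ATG, GTG, TTG} together with the stops {TAA, TAG, TGA}. With this
  six-codon set, exhaustive enumeration of ordered codon pairs yields 124
  one-base silent, 356 one-base non-silent, 12 three-base silent and 1400
  three-base non-silent changes — the class sizes of the mutation space
  this model is built on. Excluding only ATG does not produce a consistent
  classification of this kind. The set is configurable
  (`codon_table(start_codons=, stop_codons=)`); translation always follows
  the standard genetic code regardless of the start set.
* **The two-base split.** Our enumeration gives 22 silent / 1392
  non-silent two-base pairs. Class sizes of 20/1394 with the same total
  (1414) have been reported elsewhere for this decomposition; the
  discrepancy lies in the silent/non-silent assignment of a handful of
  two-base pairs, not in the enumeration itself. Since both one-base and
  three-base classes agree exactly and the two-base categories are
  unconstrained anyway (C3 accepts any two-base change), `codon_census()`
  reports both buckets as enumerated and tests pin only their sum.

## Budget, apportionment and sampling

For a gene of length $L$ and mutation level $I$ (percent), the base budget
is $N = \mathrm{round}(L \cdot I/100)$, rounded half away from zero (the
convention must be fixed somewhere; half-away-from-zero keeps
`mutation_budget(330, 5) == 17`). Event counts $c_1..c_4$ are apportioned
proportionally to the user ratio by largest remainder and then topped up
with the cheapest allowed category until
$c_1 + c_2 + 2c_3 + 3c_4 = N$ exactly; the procedure is deterministic, and
budgets that no combination of allowed categories can represent (e.g.
$N=1$ with ratio 0:0:0:1) raise an error rather than being silently
adjusted.

Codon positions are sampled uniformly without replacement among the
internal codons (first and last codon are never touched, mirroring the
start/stop exclusion), skipping codons whose current triplet is in the
excluded set. Each selected codon is mutated at most once, which makes the
nucleotide identity between donor and mutated copy exactly $100 - 100N/L$
— an invariant the tests rely on. Categories are assigned most-constrained
first (C1 before the rest) against a random permutation, passing over
codons with an empty target set for that category (TGG has no synonymous
one-base neighbour); if a category cannot be filled, the error names it.
The mutation target is drawn uniformly from the category's precomputed
neighbour set.

At high levels the no-repeat policy caps feasibility: an all-C1 plan at
$I=30$ must find silent targets for 90% of a gene's codons. This is the
package's deliberate trade-off — exactness of the identity guarantee over
unbounded levels — and failures are loud, never silent re-draws of the
whole plan.

## Insertion coordinates

Breakpoints are 1-based "insert after this base" positions (0 = before the
first base) **in original coordinates**; cassettes are applied
right-to-left per sequence so later insertions never shift earlier
recorded positions. This makes the insertion report a complete inverse:
`excise_insertions()` removes cassettes in ascending position order and
restores the recipient byte-exactly, which the suite verifies per seed and
per mode. Uniform mode samples positions over the concatenated replicon
lengths, so longer replicons receive proportionally more insertions;
intergenic mode samples annotated gaps (the complement of GFF3 feature
intervals, via `rtracklayer`/`IRanges`) and cuts each selected gap at its
midpoint. Cut points are sampled without replacement. Cassettes are
inserted forward-strand as supplied.

## Read simulation

"Insert size" means the total fragment length, so 100 bp mates at 250 bp
insert leave a 50 bp inner gap and 250 bp mates at 250 bp insert overlap
completely. Fragments have exactly the insert length (an optional normal
jitter, `insert_sd`, defaults to 0), never wrap sequence ends, and are
error-free: R1 is the fragment prefix, R2 the reverse complement of its
suffix. A member is chosen per pair with probability proportional to
abundance × genome length, so equal abundances give even *depth* rather
than even pair counts. Qualities are written as constant Q40 since no
error model applies. `simulate_reads_to_fastq()` generates in chunks so
memory stays bounded regardless of the pair count.

## The recovery criterion

A planted transfer is recovered if (i) a hit of the transferred cassette
against some contig survives identity ≥ 99% and query coverage ≥ 99%, and
(ii) at least one contig region flanking the matched interval is strictly
longer than 1000 bp (1001 qualifies, 1000 does not) and matches the
recipient genome. Where several hits qualify, the best one is used
(highest bit score, ties by longer alignment, then lexicographic contig
id). Thresholds are parameters; the defaults encode the published
criterion.

"Matches the recipient genome" needs an operational rule, and none is
standard. The default matcher declares a match when a contiguous window
covering ≥ 95% of the flank occurs exactly (either strand) in the
recipient — on error-free data this behaves like an alignment at ≥ 99%
identity and ≥ 95% coverage without requiring an external aligner, and the
5% slack tolerates a short foreign margin such as the inserted flanking
string. When real aligner output is available, a hit table can be supplied
instead and the same thresholds apply. Both are configurable.

## The fixture generator

Fixtures emulate the benchmark's shape — donor genes transferred into a
set of recipient genomes sequenced at equal abundance — at a reduced
default scale (20 genes, 3 recipients of 200 kb) chosen so the full
pipeline runs in seconds. Donor genes are random CDS: a start codon,
internal codons drawn uniformly from the non-excluded set, a stop codon.
Codon counts are multiples of 20 (lengths multiples of 60 bp), which makes
the budget $N$ a multiple of 3 at every mutation level that is a multiple
of 5 — so every generated gene admits an exact plan under any category
ratio, including three-base-only mixes, at all standard benchmark levels.
Recipient genomes are i.i.d. bases at a requested GC content with
non-overlapping 900 bp features spaced ≥ 200 bp apart, leaving genuine
intergenic gaps.

`perfect_contigs()` plays the role of an ideal assembler: one contig per
insertion, the cassette plus a fixed amount of recipient context on each
side. The context is sliced from the *original* recipient sequence, which
guarantees pure recipient-derived flanks even when two insertions happen
to fall within a context length of each other; with context 1500 every
transfer is recoverable, with context ≤ 1000 none is, giving the evaluator
a sharp two-sided oracle.

What passing on these fixtures does **not** show: real genomes have
repeats, skewed codon usage, and uneven coverage, and real assemblers
fragment contigs in ways ideal contigs never do. Recovery counts from real
assemblies depend on the assembler and its version; the shipped harness
script reproduces that part of the benchmark externally and nothing in the
test suite asserts its output.

## Problem sizes and numerical choices

The test suite runs the mutation exactness checks on 200 generated genes
of 150–300 codons across levels 0–30% and four ratios, the identity sweep
on 100 genes, read-simulator checks at 10^5 pairs over 1 Mbp, and recovery
checks on communities of ~20 genes over 3 × 200 kb recipients — sizes at
which every stochastic property tested is far from its noise floor while
the whole suite stays fast. Derived sub-seeds (`derive_seed()`) give every
pipeline stage its own RNG stream under one master seed, so adding a stage
never perturbs another stage's draws; all randomised tests fix their
seeds. Ties and degenerate inputs are resolved deterministically
throughout (empty sequences translate to the empty protein and count as
100% identical; zero-level plans return the input unchanged; empty reports
are header-only files).

## Known limitations

* No insertions/deletions and no evolutionary models (K80/GTR, dN/dS);
  divergence is uniform across the gene body by design.
* A codon is mutated at most once, capping the feasible level (see above).
* Circular replicons are treated as linear by the read simulator.
* The flank matcher is exact-substring-based; for reads or contigs with
  sequencing errors an external aligner's hit table should be supplied.
* Replacement-style (recombination) transfer is not modelled — insertions
  are purely additive.
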