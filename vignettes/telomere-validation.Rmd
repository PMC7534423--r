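---
title: "Discovering and validating telomeric repeat units with telotru"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and validating telomeric repeat units with telotru}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telotru)
```

## The problem

Chromosome-scale assemblies increasingly reach into heterochromatin, but an
assembly that *claims* to end at a telomere needs independent support. For
organisms whose telomeres are tandem arrays of a short repeat unit, two
questions arise:

1. **Discovery** — what is the repeat unit at the assembled chromosome
   termini? A tandem unit has no intrinsic phase or strand, so "the" unit is
   only defined up to rotation and reverse complement.
2. **Validation** — do raw long reads independently support that the
   assembly extends to the telomeres? A read containing a true telomere
   must *start or end* with the repeat array; a read sampled from inside
   the chromosome must not. Two artifacts confound the count: interstitial
   (subtelomeric) copies of the repeat tens of kb inside a chromosome, and
   chimeric reads that fuse fragments from two loci and can carry a
   terminal-looking array without supporting any telomere.

`telotru` implements this discovery-and-validation workflow for mosquito-style
genomes whose telomeres are tandem arrays of a ~30 bp unit, such as the
31 bp unit `GTTCCTATAGCTTCTCTCACTCAAGTAGCCT` at *Anopheles albimanus*
chromosome ends, and ships a ground-truthed simulator so every stage is
testable without external data.

## The model and its pieces

### Canonical units

`canonicalizeUnit()` maps a unit to the lexicographically smallest string
over all rotations of both strands. This single representative makes units
comparable across ends, strands and phases: the unit above and its
hybridization-probe complement `AGGCTACTTGAGTGAGAGAAGCTATAGGAAC`
canonicalize identically.

```{r canon}
canonicalizeUnit("GTTCCTATAGCTTCTCTCACTCAAGTAGCCT") ==
  canonicalizeUnit("AGGCTACTTGAGTGAGAGAAGCTATAGGAAC")
```

### Periodicity detection

`detectPeriod()` scores each candidate period $p$ by the shifted-match
fraction $f(p) = \frac{1}{n-p}\sum_i [s_i = s_{i+p}]$ (N never matches) and
returns the smallest *primitive* $p$ with $f(p) \ge$ `min_match`; $p$ is
non-primitive when a proper divisor $d$ has $f(d) \ge$ `min_match` $- 0.02$.
The 0.02 margin keeps a 31 bp unit from being reported as 62 bp while
tolerating the slight noise advantage a longer shift enjoys. The default
search range [6, 2000] bp covers both ~30 bp units and the several-hundred-bp
satellite units known from related mosquitoes; `min_match = 0.8` tolerates
residual error in polished long-read assemblies.

A terminal array typically fills only part of a terminal window (a ~3 kb
array in the default 20 kb window would dilute $f$ below any sensible
threshold), so `detectTerminalPeriod()` probes a doubling ladder of
terminus-proximal prefixes (1, 2, 4, 8 kb, then the full window), capping
the period range at a third of each prefix, and reports the first prefix
that shows a period. The shortest-prefix-first order means a short-period
terminal array is judged on the window it actually occupies.

### Consensus from variant copies

`consensusUnit()` aligns observed unit copies (which vary by substitutions
and single indels, e.g. 30/31/32 bp forms) and calls a column-majority
consensus. The minimal-rotation representative of a *mutated* copy can land
in a different phase than the true unit's — a single substitution can
change which rotation is smallest — so copies are re-phased to the modal
canonicalized copy by minimal edit distance over all rotations and strands,
then star-aligned against it. Ties between bases break alphabetically
(A < C < G < T); a deletion column requires a strict majority, an insertion
more than half of the copies. The modal seed makes the result independent
of input order; variants are stored verbatim so reports can show them in
their observed phase.

### Array annotation

`annotateArrays()` replaces an external repeat-masking step with a native
seed-chain-score scan: exact 12-mers drawn from the unit tandem (covering
every rotation, both strands) are matched along the sequence, hits within
`max_gap` (default two unit lengths, the unit-dimer scale, so a
substitution-dense patch cannot split one array into two calls) are
chained, and each candidate region
is scored by a single semi-global alignment against a tandem concatenation
of the unit. Identity is matches over alignment columns, so indels count
against it — one unambiguous definition. Arrays below `min_identity`
(0.75 for raw reads, 0.9 for assemblies) or `min_copies` (3) are dropped.
A 12-mer survives 10% per-base error with probability
$\approx 0.9^{12} \approx 0.28$ per position, so a 3-copy (~93 bp) array
essentially always receives seeds. Overlapping candidates on opposite
strands are resolved toward the longer, then higher-identity, array so
emitted intervals are always disjoint.

`findInterstitialLoci()` reports arrays lying entirely more than
`interstitial_min_distance` (default 10 kb) from both chromosome ends —
at desk scale this cleanly separates terminal arrays from subtelomeric
loci that sit ~78 kb inside.

### Read classification

`classifyRead()` decides, per read: `no_array` when no array is annotated;
`chimeric` when unique-k-mer anchors place two read segments on distinct
arms with at least `min_chimera_span` (10 kb) anchored span each;
otherwise each array is projected onto the assembly through its nearest
flank anchors, arrays landing within `flank_window` (5 kb) of a known
interstitial locus are discarded, and a surviving array within
`terminal_tolerance` (500 bp — read ends carry adapter/noise; set 0 for
strictness) of the read start or end yields `telomere_at_start` /
`telomere_at_end`. Reads whose flanks anchor nowhere, or whose array
touches both ends, are `ambiguous` and never counted as support; anything
else is `interstitial`. The per-array projection means a long read can
span an interstitial locus *and* a true terminus and still be counted as
telomere support from the terminal array, while a read whose only array
derives from the locus is excluded — the same precedence the truth labels
of the simulator use (chimeric > telomere > interstitial > no array).

Anchors are k-mers (default k = 21) occurring exactly once genome-wide,
with a k-mer and its reverse complement collapsed to one key; they are
encoded as base-4 integers in doubles (exact for k ≤ 26), so matching is
collision-free. The anchor-vote procedure is this package's defined
stand-in for the read-to-chromosome matching that terminus-validation
studies typically perform with an aligner; the majority-anchor arm of the
flank is the read's arm.

`summarizeSupport()` then counts, per arm, reads beginning and terminating
with the unit and their mean length, excluding chimeric, interstitial,
ambiguous and array-free reads, and records the length filter as a
footnote. `filterReadsByLength()` is strictly greater-than ("longer than
40 kb" read literally).

## The simulator: what it emulates and what it does not

`simConfig()` defaults define the study conditions at desk scale: five
300 kb arms (X, 2R, 2L, 3R, 3L) instead of a 172.6 Mb genome; 100 copies
of the 31 bp unit per terminus (3.1 kb arrays — "kilobases in length") at
2% per-copy divergence; interstitial loci 77.8 kb inside 2L and 78.1 kb
inside X; reads of mean 55 kb (sd 8 kb, floor 40 kb, matching the 54–61 kb
mean lengths such filters produce) at 5× coverage; 10% total error split
4/3/3% substitution/insertion/deletion; 1% chimeras fused head-to-tail
from two distinct arms with independent orientations. The two terminal
arrays of an arm run in opposite orientations, as telomeric repeats do.
Full-genome scale and the study's ~32× coverage are unnecessary for
correctness testing; 5× of 1.5 Mb keeps the whole acceptance suite within
minutes on one CPU. Truth labels are geometric, and a terminal or
interstitial array counts toward a read's truth label only when the read
contains at least three unit copies of it — mirroring the annotator's
emission floor, since a sub-3-copy sliver is undetectable by construction.

The error model is independent per-base substitution/insertion/deletion
with no homopolymer bias, no quality-value correlation, and no coverage
bias; chimeras are simple two-segment fusions. Passing tests on these
reads therefore show correctness of the algorithms under idealized noise,
not robustness to every real-ONT artifact (systematic homopolymer error,
adapter remnants, multi-segment chimeras).

## Numerical and design choices

* Coordinates are 1-based closed inside the package (the
  GenomicRanges/IRanges convention); BED output is 0-based half-open.
* Alignment scoring is match +2 / mismatch −2, gap open 4, gap extend 2 —
  edit-distance-like, adequate for ~10% divergent copies; N mismatches
  everything including N, so ambiguity never inflates identity.
* All randomness is seed-controlled; fixed seeds give byte-identical
  genomes, reads, and pipeline outputs. The read generator redraws a read
  (up to 5 times) if the error channel pushes it below the length floor.
* Consensus ties: bases alphabetically; deletions on strict majority only.
* Degenerate inputs: a unit longer than its target sequence annotates to
  an empty result (not an error); an assembly with no periodic termini
  flows through the pipeline with every read `no_array` and exit 0.
* Thresholds replace database-size-dependent E-value cutoffs on purpose:
  identity and copy-number floors are reproducible across datasets.

## Known limitations

* Retrotransposon-maintained telomeres (HeT-A/TART-style) have no tandem
  periodicity and are out of scope, as is telomere-length quantification
  across read populations.
* Units are limited to 5 kb by the period search; the consensus assumes
  copies within ±20% of the median length.
* Arm assignment needs unique k-mers near the array; reads confined to
  unresolved repeats stay `ambiguous` (conservative, never counted as
  support).

## A worked run

```{r run, eval = FALSE}
cfg <- simConfig(seed = 1)
sim <- simulateGenome(cfg)
rd <- simulateReads(sim, cfg)

units <- discoverTerminalUnits(sim$assembly)
unit <- RepeatUnit(names(sort(table(vapply(units, unitCanonical,
  character(1))), decreasing = TRUE))[1])

idx <- buildAnchorIndex(sim$assembly)
loci <- findInterstitialLoci(sim$assembly, unit)
keep <- filterReadsByLength(rd$reads, 40000)
cls <- classifyReads(keep, unit, idx, loci)
summarizeSupport(cls, arms = cfg$arms, min_length_note = 40000)
```

The same flow, file-in/file-out, is `runPipeline()` or the `telotru`
script under `inst/scripts/`.
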