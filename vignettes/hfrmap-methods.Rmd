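---
title: "Detecting recombination tracts and mapping selected loci in bacterial conjugation crosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recombination tracts and mapping selected loci in bacterial conjugation crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfrmap)
```

## The problem

In a conjugation cross, an Hfr donor transfers chromosomal DNA into a
recipient strain; homologous recombination integrates donor fragments into
the recipient chromosome. When recombinants are selected for a donor allele
(for example a functional *galK* gene on galactose medium), every surviving
clone carries a donor-derived tract covering the selected locus, usually
together with additional passenger tracts nearby. Two analysis problems
follow:

1. **Per-clone tract detection** — given short reads from one sequenced
   recombinant plus the donor and recipient reference genomes, delineate
   which intervals of the genome came from the donor.
2. **Pooled locus mapping** — given reads from a pool of many selected
   recombinants, localize the locus under selection from the excess of
   donor-specific sequence around it.

hfrmap implements both, plus the supporting machinery: extraction of
core-genome polymorphic sites, competitive read classification, a
mathematical model of mapping precision, and a synthetic-cross generator
that produces all inputs with machine-readable truth so every step can be
validated without external data.

## Competitive read classification

Reads are compared against both genomes simultaneously. Three outcomes
matter: a read can match both genomes equally well (uninformative, `TIE`),
match only one genome (strain-specific accessory sequence, `DONOR_ONLY` /
`RECIPIENT_ONLY`), or match both with a preference (`DONOR_BETTER` /
`RECIPIENT_BETTER`). Informative reads get a recipient-genome coordinate,
producing an ordered 0/1 sequence along the chromosome.

`classify_from_sam()` consumes a real competitive alignment (both
references in one SAM/BAM, `AS` alignment scores compared per read).
`classify_builtin()` is an aligner-free equivalent for synthetic data: a
read is placed by exact 31-mer seed lookup in either genome (donor
placements are projected through the core coordinate map) and its category
is decided by a majority vote over the alleles it carries at covered
polymorphic sites, with the vote margin as the score. On error-free reads
the two classifiers agree: a read carrying a donor allele mismatches the
recipient reference exactly where it matches the donor, so vote margin and
alignment-score margin have the same sign. The seed length of 31 makes
random k-mer collisions negligible at Mb genome scale, and a per-read seed
error is rescued by four further seed offsets.

## Polymorphic sites and synteny filtering

For the frequency-based method the donor/recipient polymorphic sites are
taken from a two-genome core alignment (XMFA, as produced by a core
aligner with the recipient as reference). Alignment blocks are filtered
before site extraction:

* blocks whose recipient span is shorter than **110 bp** are discarded —
  such micro-homologies are typically spurious matches in accessory genes;
* blocks on the minority orientation are discarded; absolute strand is
  arbitrary in an alignment, so "opposite strand" is interpreted as the
  minority orientation among blocks (majority-strand rule);
* blocks whose donor coordinates jump by more than **100 kb** relative to
  the previous retained block are discarded. The distance is measured on
  the donor side while scanning in recipient order: recipient-side gaps
  are ordinary accessory insertions, whereas a donor-side jump signals a
  translocated or spurious homology that breaks synteny.

The filter order (length, then strand, then distance) is configurable;
the operation is idempotent. Gap columns and ambiguity codes never yield
sites. For synthetic pairs the generator's exact truth alignment bypasses
the XMFA path (`truth_blocks()`), and site extraction on it reproduces the
generator's site table exactly — the round-trip test of both components.

## Tract detection, twice

Two independent methods delineate donor tracts; their agreement on real
data is the main internal control, so both are first-class.

**Binary-label HMM.** The ordered per-read labels feed a two-state hidden
Markov model (states donor-derived / recipient-derived) with Bernoulli
emissions: `e_d = 0.95` and `e_r = 0.05` absorb sequencing errors,
boundary-straddling reads and misclassification; the per-observation
switch probability `t = 1e-3` encodes that recombination breakpoints are
rare at read resolution. Defaults are deliberate round numbers on the
correct scale rather than fitted values: with tracts spanning hundreds of
informative reads, the decoded path depends on the parameters only
through the ratio of emission to switch log-odds. An optional Baum–Welch
refinement (`hmm_em()`) is provided but off by default so that results are
a pure function of configuration. The chain is homogeneous in observation
index; a distance-scaled variant (`distance_scale`) is exposed for very
uneven site densities. Decoding is exact (Viterbi; the tests compare it
against exhaustive enumeration of all state paths), and forward–backward
posteriors flag unresolved clones — colonies that still segregate donor
and recipient genotypes — when the posterior stays intermediate
(max-posterior < 0.8 over more than 20% of observations).

**Changepoint segmentation of allele frequencies.** At every covered
polymorphic site the donor-allele frequency is computed
(`site_frequencies()`; bases matching neither allele are excluded). The
frequency series is segmented under a piecewise-constant-mean model,
minimizing within-segment squared error plus **penalty 3** per
changepoint, solved exactly by PELT (the tests compare against a naive
optimal-partitioning dynamic program). The low penalty deliberately
favours sensitivity to short tracts; on clone data the frequencies sit
near 0 and 1, so the Gaussian idealization behind the squared-error cost
is immaterial. Segments with mean frequency above 0.5 are donor tracts;
segments need at least 2 sites.

**Boundary convention.** Both methods report tract boundaries at
supporting-site coordinates — the first and last donor-allele-bearing site
of the tract — so the boundary error is bounded by the local inter-site
spacing (about 100 bp at 1% divergence). This also makes the two methods'
limits directly comparable; `compare_methods()` quantifies agreement by
per-base Jaccard index of donor territory and reciprocal-overlap matching
of individual tracts.

## Pooled mapping

`bin_pool()` tiles the genome into 1-kb bins and counts informative reads
per bin, reporting both the donor fraction and
`log10((donor + c) / (recipient + c))` with pseudocount `c = 1` (the
pseudocount only matters in bins with almost no reads of one class; it is
configurable). The selected locus is called at the centre of the argmax
bin of the log-ratio (`locate_selected_locus()`), with a reported interval
of contiguous bins within `log10(2)` of the peak; ties are flagged and
resolved leftmost. Sub-bin refinement by a quadratic fit over the peak
neighbourhood exists as an option but is off by default — at realistic pool
coverage the bin grid already dominates the error budget.
`decay_profile()` re-indexes the profile by distance to the marker and
reports left and right half-decay distances; longer recombined tracts give
slower decay. A counter-selected locus retained by the recipient produces
a sharp local minimum instead of a peak; `locate_counterselected_site()`
reports the argmin within a window around the selection peak, where donor
signal is dense enough for a minimum to be meaningful.

`insertion_density()` summarizes transposon insertion-site tables (used to
characterize Hfr libraries) in 250-kb bins by two metrics — distinct-site
density and summed read coverage — each as log2 fold-change against the
mean per-bin value of the Ter macrodomain, plus their correlation across
bins. Coverage folds in replication-associated copy-number bias on top of
insertion bias, so its fold-changes are expected to exceed the density
ones.

## The interval-intersection model

Model the marker-covering fragments of `n` selected recombinants as
i.i.d. intervals with uniform positions, conditioned on covering the
marker; the marker offset within a fragment of length `L` is then uniform
on `[0, L)`. The shared region of all `n` fragments has length
`Λn = min(U_i) + min(L_i − U_i)` and its expectation approaches

    E(Λn) = 2 μ / n,   μ = 1 / E(1/L)

for large `n`. Because `μ` is a harmonic mean, short covering fragments
dominate it: a 10% admixture of 5-kb fragments into a 200-kb population
shrinks the shared region several-fold, which is why heterogeneous
fragment lengths — counterintuitively — sharpen mapping precision.
`simulate_shared_region()` is the Monte-Carlo simulator (its law, not the
asymptotic formula, is primary); `expected_shared_region()` returns
`2μ/n` and is documented as the large-`n` limit (`E(Λ1) = E(L)`, and for
fixed `L`, `E(Λ2) = 2L/3`, both checked exactly in the tests). Genome edge
effects are ignored (fragments are small relative to the chromosome), and
an optional length-biased mode converts a raw genome-wide length
distribution into the covering-fragment law.

## The synthetic-cross generator

The generator emulates the conditions of a selected conjugation cross
and writes truth for every
layer:

* **Genome pair** — a random ancestor core with per-site substitution
  probability `divergence` (default 0.01, the scale separating *E. coli*
  phylogroup A strains); substitutions only, alternative bases uniform.
  Accessory segments of configurable length/count are inserted into
  either genome and never carry sites. Indels and rearrangements within
  the core are not simulated — the analysis consumes substitution sites
  only.
* **Recombinants** — the marker-covering tract has length drawn from a
  configurable law (default log-uniform 10–500 kb, spreading mass over
  the kb-to-Mb span such crosses produce) and uniform marker offset; extra tracts (count
  Poisson(1.2) by default, mirroring a mean of about two fragments per
  recombinant) land uniformly within a 500-kb window around the marker
  tract, or genome-wide in an optional mode mirroring the occasional
  distant integration. Extra tracts are redrawn until they are at least
  1 kb from existing tracts: fragmented incoming DNA produces distinct
  pieces, and sub-kilobase gaps would be unresolvable at read scale
  anyway. Fragments are clipped at the genome ends (linear coordinates;
  no wrap across the origin). A `forbidden` locus — a single position or
  an interval such as a 2-kb resistance cassette — emulates
  counter-selection: no tract may overlap it. Note that tracts near the
  marker are also depleted by the marker tract itself (placements within
  1 kb of it are redrawn), so a counter-selected cassette is best placed
  away from the selection peak, as in the corresponding experimental
  designs.
* **Reads** — single-end 150 bp, uniform starts, i.i.d. substitution
  errors (default 1e-3). Short-read runs are typically paired-end
  2×150, but pairing adds no information to per-read classification as
  defined here, so single-end emission suffices. True positions are recorded in read names
  for validation only.
* **Pools** — multinomial read allocation over clones proportional to
  weights, with a JSON manifest of the realized counts.

Coordinates are 1-based inside R (the Bioconductor convention; intervals
are half-open `[start, end)` pairs), and all BED output follows the BED
convention (0-based half-open) via rtracklayer.

What the generator does **not** emulate — GC and coverage bias,
indel/rearrangement divergence, restriction-system fragment-size effects,
insertion-sequence dynamics — bounds what the tests show: they validate
the inference machinery under the model's own assumptions, not robustness
to every artefact of real sequencing data. The real-data entry points
(XMFA, SAM/BAM, BED, TSV) are the supported route for such data.

## Numerical choices and degenerate inputs

* Empty label series, empty site tables and all-empty profiles return
  empty results or explicit errors rather than guesses; fewer than two
  usable sites yield a single segment.
* Site tables drop zero-coverage sites before segmentation; duplicate
  sites at one recipient position keep the first record.
* Viterbi ties are broken towards the donor state deterministically;
  changepoint ties towards the earliest candidate start. Both are
  measure-zero events on noisy data.
* The log-ratio pseudocount, peak-interval drop (`log10(2)`), HMM
  parameters, changepoint penalty, bin sizes and identity-run thresholds
  (20/27 bp) are all exposed in `pipeline_config()`.
* Every simulation function takes an explicit seed and restores the
  caller's RNG state; pipeline runs are bitwise reproducible and write
  their resolved configuration next to their outputs.

## Problem sizes used in the test suite

Unit tests run on 20–200 kb genomes. The whole-pipeline checks use a
cross-scale fixture: a 1 Mb genome at 1% divergence with 150-bp reads at
1e-3 error — 50 clones at 100× aggregate coverage for pooled mapping, 10
clones at 10× for per-clone tract recovery, and a 20× clone downsampled to
{50, 40, 25, 17.5, 10}% for the coverage-robustness check. These sizes
keep the full suite in the minutes range on a single CPU while preserving
the relevant statistical regime (inter-site spacing ~100 bp, tracts
spanning tens to thousands of informative reads).

## Known limitations

* The built-in classifier requires exact seed matches; at divergences far
  above a few percent, or with indel-rich genomes, use a real aligner and
  `classify_from_sam()`.
* Tract detection below the inter-site resolution (gene-conversion-scale
  events) is out of scope, as are accessory gain/loss calling and
  phasing.
* The interval model ignores chromosome circularity and selection-strength
  effects; it describes strong selection at a single locus.
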