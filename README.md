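# hfrmap

Analysis of bacterial conjugation crosses: detection of donor-derived
recombination tracts in sequenced recombinant clones, and mapping of loci
under selection from pooled recombinant sequencing.

## The problem

When an Hfr donor strain conjugates with a recipient and recombinants are
selected for a donor allele (say, a functional *galK* gene), each
surviving clone carries a donor-derived tract covering the selected locus
— anywhere from ~1 kb to over 1 Mb long — often with additional passenger
tracts nearby. hfrmap answers two questions for such crosses:

1. **Which parts of a sequenced recombinant genome came from the donor?**
   Reads are mapped competitively against both parental genomes and each
   informative read is labeled donor-better (1) or recipient-better (0).
   Tracts are then delineated by two independent methods:
   a two-state hidden Markov model on the ordered binary labels
   (Bernoulli emissions `e_d`/`e_r`, switch probability `t`, exact
   Viterbi decoding), and penalized changepoint segmentation of the
   donor-allele frequency at core-genome polymorphic sites (piecewise
   constant mean, SSE cost + penalty 3 per changepoint, solved exactly
   by PELT). Their concordance is the built-in control.

2. **Where is the locus under selection, from a pool?** Informative reads
   from a sequenced pool of recombinants are counted in 1-kb bins; the
   selected locus is called at the maximum of
   `log10((donor + 1)/(recipient + 1))` along the genome. A
   counter-selected cassette retained by the recipient appears as a sharp
   local minimum instead.

The precision of pooled mapping is governed by the interval-intersection
model: with `n` selected recombinants whose marker-covering tract lengths
`L` have harmonic mean `μ = 1/E(1/L)`, the donor region shared by all
recombinants has expected length

```
E(Λn) = 2 μ / n
```

for large `n`. Short tracts dominate the harmonic mean, so heterogeneous
tract lengths sharpen — not blur — the localization.

Polymorphic sites come either from a two-genome core alignment (XMFA,
with synteny filters: blocks < 110 bp, donor-coordinate
jumps > 100 kb, and minority-strand blocks removed) or from the built-in
synthetic-cross generator, which produces genome pairs, recombinant
clones, reads and pools with machine-readable truth for every layer.

## Worked example

```r
library(hfrmap)

# a donor/recipient pair: 300 kb core, 1% divergence
pair <- generate_genome_pair(genome_pair_config(
  genome_length = 3e5, divergence = 0.01, seed = 42))
pair
#> genome_pair: core 300000 bp, divergence 0.01, 3089 polymorphic sites
#>   donor 300000 bp (0 accessory), recipient 300000 bp (0 accessory)

# one recombinant selected at 150 kb, with two passenger tracts
clone <- simulate_recombinant(
  pair, marker_position = 1.5e5,
  marker_dist = fragment_dist("log_uniform", low = 2e4, high = 1e5),
  extra_count = 2L,
  extra_dist = fragment_dist("log_uniform", low = 5e3, high = 2e4),
  clone_id = "demo", seed = 7)
clone$fragments
#>    start    end contains_marker
#> 1  20516  26386           FALSE
#> 2 110930 209161            TRUE
#> 3 232052 239062           FALSE

# sequence it at 10x and classify the reads competitively
reads <- simulate_reads(clone$sequence, depth = 10, error_rate = 1e-3,
                        seed = 8)
cls <- classify_builtin(reads, pair)
cls
#> read_classification: 20000 reads
#>     DONOR_BETTER RECIPIENT_BETTER              TIE
#>             5892             9930             4178

# delineate the tracts by both methods and compare
frags_hmm <- hmm_segment(binary_series(cls), marker = 1.5e5)
frags_cp  <- changepoint_segment(site_frequencies(cls, pair$truth_sites),
                                 marker = 1.5e5)
subset(frags_cp, origin == "donor")
#>    start    end origin n_obs contains_marker mean_freq
#> 2  20684  26230  donor    59           FALSE 1.0000000
#> 4 111000 209110  donor  1029            TRUE 0.9995919
#> 6 232188 239005  donor    83           FALSE 1.0000000
compare_methods(frags_hmm, frags_cp)
#> method concordance: Jaccard 1.0000, 3 matched, 0 HMM-only, 0 freq-only
```

All three simulated tracts are recovered with boundaries at the flanking
polymorphic sites (compare `clone$fragments`), and the two methods agree
base-for-base. The interval model predicts how a pool of such
recombinants narrows the candidate region:

```r
simulate_shared_region(100, fragment_dist("log_uniform",
                                          low = 1e4, high = 1e6),
                       n_reps = 1e4, seed = 1)
#> shared region: n = 100, 10000 replicates
#>   mean Lambda_n = 927.2; 2*mu/n = 930.3 (mu = 46516.9)
```

One hundred selected recombinants with kb-to-Mb covering tracts share
under a kilobase of donor DNA — the locus is pinned to sub-kb precision,
and the Monte-Carlo mean matches the analytic `2μ/n`.

End-to-end runs (simulate → classify → segment/map → report files) are
`run_clone_analysis()` and `run_pool_analysis()` driven by
`pipeline_config()`; a thin command-line wrapper lives at
`inst/cli/hfrmap.R`. The methods vignette
(`vignettes/hfrmap-methods.Rmd`) documents the models, parameter
defaults, and the generator's assumptions.

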