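---
title: "Population-genetic analysis of polymorphic inversions with invpopkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-genetic analysis of polymorphic inversions with invpopkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invpopkit)
```

## The scientific problem

Polymorphic chromosomal inversions segregate in human populations as two
orientations of a genomic segment, called `O1` (the reference orientation)
and `O2`. Because a single crossover inside the inverted segment of a
heterokaryotype produces unbalanced gametes, effective recombination
between the two orientations is suppressed there: each orientation behaves
like a partially isolated sub-population of chromosomes. That suppression
is what makes inversions analytically tractable — and interesting. It
preserves the haplotype background on which each inversion arose (so
recurrent origins remain visible as distinct haplotype clusters), it lets
nucleotide divergence between orientations accumulate like divergence
between incipient species (so inversions can be dated), and it couples the
fate of linked variants to the fate of the inversion (so selection on the
inversion distorts the linked site-frequency spectrum).

`invpopkit` implements the full analysis stack around an inversion
genotype panel: linkage and tag-variant analysis, fixed/shared variant
classification and non-recombining flank definition, haplotype clustering
with minimum recurrence-event inference, Y-chromosome parsimony and
inversion-rate estimation, divergence-based dating with bootstrap
intervals, ascertainment-aware frequency analysis, selection scans
(Weir-Cockerham F~ST~, linked-site frequency-spectrum tests with
Edgington combination, NCD balancing-selection statistics), inversion
eQTL regression and GWAS-signal enrichment. A seeded synthetic-data
generator produces all the inputs at desk scale, so every stage can be
exercised, calibrated and stress-tested without external downloads.

## The synthetic-data generator

The generator (`sim_config()`, `simulate_haplotypes()`) is a Kingman
coalescent with two extensions:

* **Orientation classes.** Haplotypes belong to the `O1` or `O2` class. In
  unique-origin mode the `O2` class descends from a single lineage that
  flipped orientation a configurable number of generations ago: the `O2`
  genealogy is a coalescent conditioned to find its common ancestor more
  recently than the origin, its ancestral lineage enters the `O1`
  genealogy at the origin time, and the two coalesce at the neutral rate
  thereafter. In recurrent mode, `k` origin events are placed on distinct,
  disjoint branches of one genealogy such that the minimum-change
  reconstruction of the tip states equals `k`.
* **Recombination structure.** Exchange *between* orientation classes
  inside the inverted span is fully suppressed — the zero-exchange limit
  implied by heterokaryotype crossover selection — except for optional
  gene-conversion tracts (default length 200 bp, default rate 0; the rate
  is qualitative in the source literature, so 0 is the neutral default).
  Same-orientation chromosomes, however, do recombine: with `rho > 0` the
  inverted span is split into roughly `4 * Ne * rho * L` blocks, each
  with an independent class-structured genealogy that shares the same
  orientation membership and origin time. Flanking sequence decays away
  from the inversion genealogy: a flank segment at distance `d` keeps the
  inversion-linked genealogy with probability `exp(-4 * Ne * rho * d)`
  and otherwise receives an independent neutral genealogy.

Desk-scale parameters are chosen to preserve the *population-scaled*
rates of the system being emulated rather than the raw ones: a 30-kb human
region has `4 Ne r L` of roughly 10–15 and per-site diversity of about
0.001, so defaults such as `Ne = 1000` with correspondingly larger `mu`
and `rho` keep `4 Ne mu` and `4 Ne rho` in the human range while the
coalescent stays cheap. `simulate_neutral_pool()` emulates a genome-wide
SNP pool as many unlinked loci; a single-genealogy pool would have an
enormously variable realized frequency spectrum, which is not what a
genome-wide panel looks like.

What the generator deliberately does **not** emulate: genotyping error,
demographic structure beyond one panmictic population per labelled group,
gradual LD decay within a flank segment (the two-genealogy mixture is a
step approximation), gene flow between populations, and background
selection. Passing tests therefore show that the estimators behave
correctly under their own model assumptions — not that those assumptions
hold in any particular real data set.

## Linkage, classification, flanks

`ld_r2()` computes the textbook haplotype measure `D^2/(pA pa pB pb)` by
gamete counting when phased data are available and the composite
genotype-dosage correlation squared otherwise (phase-free; reduces to the
haplotype measure under Hardy-Weinberg proportions).
`classify_variants()` labels variants `fixed` (r^2 = 1), `shared`
(unambiguously polymorphic on both orientations), `private_O1`/
`private_O2` or `unassigned`. Without phased haplotypes, an allele is
credited to an orientation only when the genotypes force the assignment:
all alleles of inversion homozygotes and hemizygotes, and
variant-homozygous calls in inversion heterozygotes (which place the
allele on both orientations). This matches exhaustive enumeration of all
allele-to-orientation assignments consistent with the genotypes, which
the test suite checks directly.

`nonrecombining_flank()` scans outward from each breakpoint up to 20 kb
and stops before the first shared variant compatible with a crossover.
An isolated shared variant bracketed within 1 kb on both sides by
orientation-anchored variants is treated as gene-conversion evidence and
skipped; the bracket distance is a parameter. The requirement that the
flank include the fixed variants is read as a property the stopping rule
already delivers; truncation at the outermost fixed variant (or at 90% of
them) is available by flag because the operational rule in the source
material is not fully specified.

## Recurrence inference

`cluster_haplotypes()` clusters haplotypes by Hamming distance after
putting them in a canonical lexicographic order, so results are invariant
to input permutation. `estimate_recurrence()` then (1) reassigns putative
phasing errors — a labelled haplotype from an inversion-heterozygous
sample within `max_error_diff` (default 2) of an opposite-orientation
haplotype; (2) computes the minimum number of orientation changes on the
dendrogram by small parsimony (an exact per-state dynamic programme — the
Fitch-set shortcut of adding one change for a conditioned root state is
wrong, as conditioning can cost several extra changes); (3) merges
same-orientation change clusters whose minimum distance is below
`min_separation` (default 20 variants) — clusters that close do not
"differ significantly" enough to support independent origins; and (4)
reports distinct event groups minus one, since the original inversion is
not a recurrence. All three thresholds are reported in the result, never
silently applied. For recovery of coalescent clades, average linkage
(UPGMA) is the consistent choice, because coalescent trees are ultrametric
in expectation; complete linkage remains available and is the default for
display purposes.

`fitch_parsimony_events()` performs the same dynamic programme on an
arbitrary rooted tree (multifurcations allowed), optionally conditioned on
a root state, and `inversion_rate()` converts an event count and a total
branch length in generations into a rate with an exact Poisson interval.

## Dating

`pairwise_diversity()` computes mean pairwise differences per surveyed
base within and between orientation classes; the denominator is the
physical width of the requested span (the variant matrix holds the
segregating subset), or the column count when no span is given.
`estimate_age()` implements the divergence-based estimator

> age = (pi_between − max(pi_within)) / (2 × rate),

where the factor 2 reflects that divergence accrues on both lineages
since the origin and subtracting the larger within-class diversity
corrects for diversity already segregating in the ancestral background.
Non-positive net divergence is reported as a non-positive age and
flagged, never clipped. `bootstrap_age_ci()` resamples *individuals*
with replacement (1000 times by default), skipping and counting
degenerate resamples.

**Known limitation.** The individual bootstrap measures sampling
uncertainty only. For a single non-recombining locus the dominant error
of divergence dating is coalescent and mutational randomness, which is
invisible to individual resampling: in simulations at realistic age/Ne
ratios the replicate-to-replicate standard deviation of the point
estimate is several times the bootstrap-implied one, and intervals
undercover the true age badly even though they match the realized
subsampling variability almost exactly. The intervals should be read as
"uncertainty from sampling these individuals", not as full confidence
intervals for the age — the median relative bias of the point estimate
itself stays well under 15% in the tested range.

`infer_ancestral()` reduces outgroup orientation calls to a consensus:
species polymorphic for the region are uninformative (a segregating
inversion in an outgroup signals recurrence, not ancestry), and the
majority state among informative species is taken with ties returned as
`unknown` — the rule under which two agreeing deeper outgroups outvote a
single discordant closer one. A strict most-parsimonious reconstruction
was rejected because it leaves exactly that configuration ambiguous at
the human stem.

## Frequency analysis under ascertainment

Inversions were discovered in small panels before being genotyped widely,
which inflates their observed frequencies. The two-step mirror of that
process is: (1) `simulate_discovery_panel()` keeps variants polymorphic
within a discovery subset (default nine diploid individuals); (2)
`simulate_detection()` samples 10,000 variants from the surviving pool
with probability proportional to a pluggable detection model. The default
model is carrier presence evaluated on the discovery genotypes — after
step 1 it is flat, so step 2 reduces to uniform sampling, and the mean
minor-allele frequency of the ascertained set lands near 0.19–0.20 for a
neutral pool (the value `scripts/acceptance.R` recomputes). Richer
detection models (frequency- or length-dependent) plug in as functions.

`hwe_exact_test()` is the exact conditional test (full enumeration of
heterozygote counts), `empirical_frequency_test()` implements the
twice-the-extreme-fraction convention capped at one, and
`robust_regression_stepwise()` fits M-estimation (Tukey bisquare)
regressions with forward selection at robust-test p < 0.05, reporting a
robust pseudo R-squared (one minus the squared ratio of residual to total
M-scales; the exact definition in the source material is unstated, so
this choice is documented rather than hidden).

## Selection scans

`weir_cockerham_fst()` implements the 1984 variance components (a, b, c)
with a haploid moment estimator for chrY-like data.
`fst_empirical_pvalue()` places an inversion in a matched null
distribution and classifies signals as strong (top 1%), weak (top 5%) or
none. `lsfs_build()` tabulates the linked-site frequency spectrum:
variants classified `nested`, `disjoint` or `discordant` by the topology
of their carrier set relative to the inverted-allele carriers, counted in
derived/minor-frequency bins; under complete crossover suppression a
perfect genealogy contains no discordant variants, which the generator
reproduces exactly at `rho = 0`. `lsfs_linear_test()` computes a
statistic linear in the spectrum, normalized by the window's variant
count, against an empirical null bank conditioned on the focal-allele
frequency; weights are estimated from simulated alternatives
(`estimate_lsfs_weights()`: mean shift over null standard deviation —
the statistic's only contract is linearity plus empirical calibration).
Population p-values of a window combine by Edgington's method
(Irwin-Hall closed form, `edgington_combine()`); across windows both a
conservative (Bonferroni-minimum) and an approximate (Edgington)
summary are reported, as the exact combination rules in the source
material are not printed.

`ncd_statistic()` measures how tightly window minor-allele frequencies
cluster around a target frequency (0.3/0.4/0.5), with fixed differences
entering as frequency-zero sites in the NCD2 variant; windows need at
least eight informative sites and one sixth alignment coverage, and
low values are balancing-like, so the empirical p-value takes the lower
tail with the `(r+1)/(n+1)` convention. Empirical p-values from integer
counts are discrete; calibration checks hold when ties are rare, which at
desk scale means reasonably dense windows (about 20–30 variants, the
density of a 3-kb window in a large sequencing panel).

## Functional association

`rank_normalize()` maps ranks through the normal quantile function (Blom
offset). `inversion_eqtl()` regresses covariate-adjusted, rank-normalized
expression on O2 dosage for features with a transcription start site
within 1 Mb and expression in at least 20% of samples; covariates are
user-supplied columns plus expression principal components (defaults 10
for genes, 20 for transcripts), and the test degrees of freedom are
reduced by the number of covariates projected out. Benjamini-Hochberg
q-values are computed across tested features; a permutation mode
shuffles genotypes as a negative control. Under the global null the BH
procedure is a size-0.05 Simes test, so a calibrated pipeline shows zero
hits in almost exactly 95% of permutation runs — the negative control is
a calibration check, not an absolute guarantee of emptiness.
`joint_lead_eqtl()` ranks the inversion against neighbouring variants per
feature (ties break toward larger effects, then toward the inversion so a
perfectly tied tag SNP does not displace it). `cluster_gwas_loci()`
deduplicates GWAS signals by single-linkage within +/-100 kb or r^2 >=
0.8 and shared phenotype (made transitive for determinism), and
`gwas_enrichment()` compares the locus count in the inversion +/-20 kb
with 1000 random same-size regions matched on mean SNP frequency
(+/-0.01) and on the MAF<0.2 / >=0.2 composition (chi-square p > 0.05),
excluding gaps, with a one-tailed `(r+1)/(n+1)` p-value.

## Numerical choices and degenerate inputs

Coordinates are 0-based half-open everywhere internally; VCF positions
convert at the boundary. Missing genotypes are excluded pairwise.
Monomorphic vectors give `NA` LD and F~ST~; empty windows are excluded
rather than zeroed; degenerate bootstrap resamples are skipped and
counted; clustering ties break by canonical haplotype order; empirical
p-values from banks use `(r+1)/(n+1)` except where the
twice-the-fraction convention is the stated method (frequency tests).
All stochastic procedures accept explicit seeds and are bit-reproducible.

Problem sizes used by the test-suite and the acceptance script are desk
scale by design: pools of 500 diploids over 50 unlinked loci, panels of
20–60 samples, 100–200 simulation replicates, bootstrap and null banks of
150–1000 — large enough for the calibration and recovery bounds they
feed, small enough to run on one core in minutes.
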