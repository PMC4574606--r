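---
title: "Measuring and quality-controlling allelic expression from RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and quality-controlling allelic expression from RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aeqc)
```

## The measurement and its failure modes

Allelic expression (AE) quantifies the relative expression of the two
parental copies of a gene within one individual. At a heterozygous SNP
(het-SNP) covered by RNA-seq reads, each read carries either the
reference (REF) or the alternative (ALT) base, so the read counts
$(n_R, n_A)$ estimate the allelic ratio. The units used throughout are

$$\text{reference ratio} = \frac{n_R}{n_R + n_A},\qquad
  \text{AE effect size} = \left|\,0.5 - \text{reference ratio}\,\right|
  \in [0, 0.5].$$

The measurement is conceptually trivial and practically treacherous.
Every systematic error that survives counting masquerades as allelic
imbalance:

* **Double counting.** PCR/optical duplicates and mate pairs that both
  cover the site inflate counts without adding molecules.
* **Genotyping error.** A homozygous site miscalled heterozygous shows
  up as perfectly monoallelic "expression".
* **Reference mapping bias.** Reads carrying the ALT allele mismatch
  the reference genome and align less efficiently, pushing the
  genome-wide reference ratio above 0.5.
* **Depth-driven power.** Binomial significance at a fixed tiny effect
  is guaranteed at high enough coverage, so "significant AE" enriches
  in deep sites and in deeply sequenced samples.

The package implements the counting layer with strict read accounting,
the statistical layers that detect or absorb each artifact, and a
read-level simulator that reproduces each artifact with known truth so
that every stage is testable without external data.

## Counting semantics

`count_alleles()` tallies, at each het-SNP, the primary alignments with
an aligned base over the position (`raw_depth`). Reads whose alignment
spans the site with a deletion or splice gap carry no base and are
ignored. Every read in `raw_depth` lands in exactly one bucket —
`ref_count`, `alt_count`, `other_count`, `low_mapq_dropped`,
`duplicates_dropped`, `mate_conflicts_dropped`,
`overlapping_mates_merged` or `low_baseq_dropped` — so the bucket sums
equal `raw_depth` at every site. This conservation identity is enforced
by the test suite on randomized simulations; it is the property that
makes the diagnostic columns trustworthy.

Filters are applied in this order:

1. secondary/supplementary alignments are excluded outright (they are
   not molecules; together with the mapping-quality threshold, default
   20, this enforces unique mapping);
2. duplicates are collapsed to one representative per group. Groups
   come from the SAM duplicate flag when the file has one, else from
   the signature (strand, unclipped start, mate start). The retained
   read is chosen uniformly at random or by base quality at the site
   (ties broken randomly), **never** by mapping score — reference
   reads systematically win mapping-score comparisons, which would
   re-introduce the very bias the pipeline fights;
3. mate pairs that both cover the site are counted once per fragment:
   concordant calls keep the higher base quality, discordant calls
   discard the fragment (both reads are tallied as conflicts so the
   accounting stays exact);
4. the base-quality threshold (default 10) is applied to the effective
   quality; surviving bases classify as REF, ALT or other (`N` counts
   as other).

Random choices consume a dedicated stream seeded by
`counting_options(rng_seed=)`, so counting is reproducible.

A boundary convention worth stating: site-filter masks
(`apply_site_filter()`) treat the interval end as exclusive with
respect to the 1-based site position — a site whose position equals an
interval's `end` coordinate is retained. Chromosome naming styles
("chr1" vs "1") are never harmonized silently; a mismatch is an error.

## The genotype-error test

Under the null hypothesis that a site is homozygous, minor-allele reads
arise only from sequencing/alignment noise. The per-library noise rate
is estimated from reads assigned to *neither* REF nor ALT:

$$\hat\varepsilon = \frac{\sum_i \text{other}_i}{\tfrac12 \sum_i
  \text{total}_i},$$

excluding sites with more than 5 % other-allele reads (strictly
greater), which reflect systematic problems rather than baseline noise.
The factor $\tfrac12$ converts the two-off-target-bases rate into a
per-allele rate. The homozygosity tail sum is

$$p_{\text{hom}} = \min\!\big(1,\; P(X \ge n_A) + P(X \ge n_R)\big),
  \qquad X \sim \mathrm{Bin}(n_R + n_A,\, \varepsilon),$$

with the inclusive tail $P(X \ge k) = 1 - \mathrm{BinCDF}(k - 1, n,
\varepsilon)$, matching the verbal definition "$n_A$ *or more* reads";
the exclusive variant ($1 - \mathrm{BinCDF}(k, n, \varepsilon)$) is
available via `inclusive = FALSE` for replicating pipelines built on
that convention. `flag_genotype_errors()` corrects across sites with
Benjamini–Hochberg and flags sites where homozygosity is *not*
rejected. Monoallelic low-count sites are flagged by construction:
homozygosity is unrejectable and heterozygosity unsupported. The flag
cannot distinguish genotyping error from genuinely monoallelic biology
(imprinting, nonsense-mediated decay); that interpretation is the
user's.

Under the simulator's error model (substitutions uniform over the three
non-template bases at per-base rate $e$), other-allele reads appear at
rate $2e/3$ and the estimator's expectation is $4e/3$ — intentionally
above the $e/3$ rate at which noise produces a *specific* wrong allele,
so the test errs conservative.

## AE statistics

`binomial_ae_test()` is the exact two-sided binomial test. At the
symmetric null it is the doubled smaller tail capped at 1; at other
nulls it is the minimum-likelihood convention (all outcomes no more
likely than the observed one), identical to `stats::binom.test`, which
the test suite uses as an independent cross-check. The floating-point
tie tolerance (`1 + 1e-7` relative) follows the same convention.

The binomial null can be the classic 0.5 or the sample's
`global_reference_ratio()` — by default the **unweighted mean of
per-site ratios** ("per base"), so deep sites do not dominate; a
read-weighted variant exists because the phrase is ambiguous in common
usage. Testing against the global ratio absorbs residual reference
mapping bias left after site filtering.

Two defences against depth-driven significance are provided:
`scale_counts()` subsamples each site to a fixed depth (default 30)
*without replacement* — reads are finite physical observations, and
with-replacement sampling would inflate variance at shallow sites —
and `call_significant_sites()` can require a minimum effect size
(0.15 is the conventional choice) on top of the BH q-value.

Default analysis thresholds: total counts of at least 30 for
significance testing, at least 8 for QC summaries, at least 16 for
gene-level AE; all configurable. The 8-read QC threshold is applied
after fragment merging (the merged count is the molecule count).

## Between-sample distances and the eQTL validation

The distance between samples is the fraction of shared AE sites
significant in exactly one of the two; "shared" means tested (depth and
QC passed) in both. `classical_mds()` is Torgerson scaling
(`stats::cmdscale`) with negative eigenvalues truncated to zero under a
warning — the AE distance is not guaranteed Euclidean.

`gene_level_ae()` takes the median effect size over a gene's qualifying
sites (sites inside several overlapping genes count toward each — the
alternative silently drops data), and `compare_het_vs_hom()` applies a
Wilcoxon rank-sum test per gene between eSNP heterozygotes and pooled
homozygotes, requiring a minimum number of measurements per class
(default 30) and BH across genes (default 1 % FDR). The expected
direction of genuine cis-regulatory signal is higher AE in
heterozygotes; significant genes in the opposite direction are an
artifact readout.

## What the simulator emulates — and what it does not

`simulate_sample()` plants REF/ALT bases at isolated het-SNPs in reads
drawn from a synthetic reference, with knobs for each artifact: per-base
substitution errors (uniform over the three non-template bases), PCR
duplicate cloning (flagged, independent re-sequencing errors),
mate-overlap fraction, truly homozygous sites inside the "het" list,
and reference bias as post-hoc thinning of ALT fragments at retention
probability $b$ — which gives the closed-form pooled ratio expectation
$0.5 / (0.5 + 0.5b)$ used in recovery tests. Geometry is stylized so
bookkeeping is exact: sites are spaced beyond any fragment span,
overlap fragments get inserts shorter than two read lengths with the
site inside the overlap, all others at least two read lengths.
`simulate_counts()` is a counts-level twin sharing the same observation
model, used where only the statistics are under test (large calibration
runs); agreement between the two routes is itself tested.

Deliberately not modelled: transcript structure and splicing,
expression-level variation across genes, aligner behaviour (bias is
thinning, not mis-mapping), indels, and haplotype sequence context.
Passing tests therefore demonstrate the correctness of counting and
statistics under controlled artifacts, not robustness to every
property of real libraries — in real data, overdispersion beyond the
binomial and residual locus-specific bias remain, which is why the
effect-size cutoff and the monoallelic flag matter in practice.

## Numerical and experimental choices

* Exactness: both binomial tests agree with term-by-term probability
  mass summation to well below $10^{-12}$ over depth grids up to 200.
* Calibration is checked at 10,000 sites of depth 5,000. The exact
  test is discretely conservative: at depth 30 the $p<\alpha$ fraction
  is theoretically 0.0052/0.043/0.099 for $\alpha$ = 0.01/0.05/0.10,
  i.e. visibly below $\alpha$ at the lower levels. At depth 5,000 the
  theoretical fractions (0.0096/0.0493/0.0980) are within three
  binomial standard errors of nominal, so that depth is where the
  calibrated-limit property is meaningfully testable.
* The laboratory-clustering analogue uses two simulated labs of six
  samples at depths 100 and 300 over 400 shared sites with
  Beta-distributed true ratios (spread 0.05). Both labs then have full
  power for effects above 0.15, which is the regime in which the
  effect-size cutoff actually removes the depth signature; with a
  shallower lab the cutoff cannot mix the labs because power, not the
  cutoff, limits its calls.
* The eQTL validation analogue uses 24 individuals, 40 eGenes of two
  sites each at depth 30, het effect 0.15, with 15 % genotype errors,
  30 % duplicates and ALT retention 0.85 injected; classes are
  compared at 8 or more measurements per class. These sizes keep the
  full cohort simulation in tens of seconds while leaving the QC
  contrast far from ceiling: in the fixed-seed run the post-QC
  pipeline recovers 23/34 true-direction genes against 3/35 without
  QC, with no opposite-direction calls in either.
* Duplicate-representative uniformity is verified over 10,000 seeded
  draws (binomial 99 % interval half-width 1.5 percentage points).

## Limitations

Counting is implemented in portable R over `Rsamtools::scanBam`; it is
intended for the site-list scale typical of AE work (thousands to tens
of thousands of het-SNPs), not whole-genome pileup. Beta-binomial
overdispersion models, haplotype-aggregated tests and multi-sample
hierarchical models are intentionally out of scope; the package's
statistics are the exact binomial layer those models build on. The
genotype-error flag is per sample; designs with multiple tissues of one
individual can intersect flags across samples but no joint test is
provided.
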