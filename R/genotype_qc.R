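# Genotype-error detection from allelic counts.
#
# A homozygous site miscalled as heterozygous shows up as (near-)
# monoallelic AE. Under homozygosity, reads supporting the second allele
# arise only through sequencing/alignment noise, whose per-library rate
# epsilon is estimated from reads supporting neither REF nor ALT.

#' Estimate the per-library sequencing noise rate
#'
#' The noise rate epsilon is the ratio of the total number of
#' other-allele reads (neither REF nor ALT) to half the total number of
#' reads across sites. Sites where more than 5 % of assigned reads
#' support other alleles are excluded from both sums — such sites are
#' dominated by systematic artifacts, not baseline noise. The per-site
#' denominator for the 5 % rule is the reads actually assigned at the
#' site after quality filters (ref + alt + other).
#'
#' @param counts A `site_counts` table.
#' @return An object of class `"noise_estimate"`: a list with `epsilon`,
#'   `other_allele_reads`, `total_reads`, `sites_used`, `sites_excluded`.
#' @export
estimate_noise_rate <- function(counts) {
  if (!is.data.frame(counts) || nrow(counts) == 0L)
    stop("counts must be a non-empty site_counts table")
  site_total <- counts$ref_count + counts$alt_count + counts$other_count
  covered <- site_total > 0L
  frac_other <- ifelse(covered, counts$other_count / site_total, 0)
  eligible <- covered & frac_other <= 0.05
  excluded <- covered & frac_other > 0.05
  other_sum <- sum(counts$other_count[eligible])
  total_sum <- sum(site_total[eligible])
  if (total_sum == 0L) {
    warning("no eligible reads; epsilon set to 0")
    eps <- 0
  } else {
    eps <- other_sum / (total_sum / 2)
  }
  structure(list(epsilon = eps,
                 other_allele_reads = other_sum,
                 total_reads = total_sum,
                 sites_used = sum(eligible),
                 sites_excluded = sum(excluded)),
            class = "noise_estimate")
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf(
    "Noise rate epsilon = %.3g (%d other-allele reads / (%d reads / 2); %d sites used, %d excluded at >5%% other)\n",
    x$epsilon, x$other_allele_reads, x$total_reads,
    x$sites_used, x$sites_excluded))
  invisible(x)
}

#' Binomial test of homozygosity at an apparently heterozygous site
#'
#' Under the null hypothesis that the site is homozygous for one allele,
#' reads of the second allele occur at the noise rate `epsilon`, so the
#' observed counts are extreme when either tail probability is small.
#' The returned value is
#' `min(1, P(X >= n_A) + P(X >= n_R))` with `X ~ Binomial(n_R + n_A,
#' epsilon)`: the chance of observing this much support for the minor
#' allele under homozygosity for either allele. Small values reject
#' homozygosity (a genuine het); values near 1 mean homozygosity cannot
#' be excluded.
#'
#' `inclusive = TRUE` (default) reads "n_A or more" as the inclusive
#' tail `1 - BinCDF(n_A - 1, n, eps)`; `inclusive = FALSE` uses the
#' exclusive convention `1 - BinCDF(n_A, n, eps)` for exact replication
#' of pipelines written against that convention.
#'
#' @param n_R,n_A Reference / alternative read counts (vectors recycle).
#' @param epsilon Noise rate in `[0, 1)`.
#' @param inclusive Tail convention, see Details.
#' @return Tail-sum probabilities in `[0, 1]`.
#' @examples
#' homozygosity_test(30, 0, 0.01)   # ~1: monoallelic, hom not rejected
#' homozygosity_test(15, 15, 0.01)  # ~0: balanced, genuine het
#' @export
homozygosity_test <- function(n_R, n_A, epsilon, inclusive = TRUE) {
  if (any(n_R < 0) || any(n_A < 0)) stop("read counts must be non-negative")
  if (any(epsilon < 0) || any(epsilon >= 1)) stop("epsilon must be in [0, 1)")
  n <- n_R + n_A
  if (any(n < 1)) stop("n_R + n_A must be at least 1")
  shift <- if (inclusive) 1L else 0L
  tail_A <- pbinom(n_A - shift, n, epsilon, lower.tail = FALSE)
  tail_R <- pbinom(n_R - shift, n, epsilon, lower.tail = FALSE)
  pmin(1, tail_A + tail_R)
}

#' Flag probable genotyping errors among het-SNP counts
#'
#' Applies [homozygosity_test()] at every site, corrects across sites
#' with Benjamini-Hochberg, and flags the sites where homozygosity
#' cannot be rejected at the given FDR. Fully monoallelic sites with low
#' counts are flagged by construction (their tail sum is ~1):
#' homozygosity is not rejected and heterozygosity is unsupported.
#' Interpretation is left to the user — a flagged site is either a
#' genotype error or genuinely monoallelic biology (imprinting, NMD);
#' the two cannot be distinguished from one sample.
#'
#' @param counts A `site_counts` table.
#' @param epsilon Noise rate; when `NULL`, estimated from `counts` via
#'   [estimate_noise_rate()].
#' @param fdr False-discovery rate for rejecting homozygosity.
#' @param min_depth Sites with fewer than this many ref+alt reads are
#'   excluded from testing (0 tests every site).
#' @return A `data.frame` with the site columns plus `n_R`, `n_A`,
#'   `p_hom`, `q_value`, `flagged`, in input order; attribute `epsilon`.
#' @export
flag_genotype_errors <- function(counts, epsilon = NULL, fdr = 0.01,
                                 min_depth = 0L) {
  stopifnot(fdr > 0, fdr < 1)
  if (is.null(epsilon)) epsilon <- estimate_noise_rate(counts)$epsilon
  if (inherits(epsilon, "noise_estimate")) epsilon <- epsilon$epsilon
  df <- as.data.frame(counts)
  keep <- df$total_count >= min_depth & df$total_count >= 1L
  df <- df[keep, c("chrom", "pos", "site_id", "ref", "alt",
                   "ref_count", "alt_count"), drop = FALSE]
  names(df)[names(df) == "ref_count"] <- "n_R"
  names(df)[names(df) == "alt_count"] <- "n_A"
  df$p_hom <- homozygosity_test(df$n_R, df$n_A, epsilon)
  df$q_value <- p.adjust(df$p_hom, method = "BH")
  df$flagged <- df$q_value > fdr  # homozygosity NOT rejected
  rownames(df) <- NULL
  attr(df, "epsilon") <- epsilon
  df
}

#' Fraction of het-SNPs with reads observed from both alleles
#'
#' A sensitive per-sample genotype-quality metric: genuine het sites
#' with adequate coverage should nearly always show both alleles, so a
#' depressed fraction indicates genotyping error (or contamination).
#'
#' @param counts A `site_counts` table.
#' @param min_depth Minimum ref+alt reads for a site to qualify.
#' @return The fraction in `[0, 1]`, or `NA` (with a warning) when no
#'   site qualifies.
#' @export
both_alleles_observed_fraction <- function(counts, min_depth = 8L) {
  qual <- counts$total_count >= min_depth
  if (!any(qual)) {
    warning("no sites at the required depth; fraction undefined")
    return(NA_real_)
  }
  mean(counts$ref_count[qual] > 0L & counts$alt_count[qual] > 0L)
}

#' DNA-RNA heterozygosity concordance
#'
#' Among DNA-heterozygous sites with adequate RNA coverage, the fraction
#' whose lesser-covered allele has at least `min_minor_reads` reads —
#' i.e. sites that look heterozygous in the RNA as well. With
#' `min_minor_reads = 1` this reduces to
#' [both_alleles_observed_fraction()].
#'
#' @param counts A `site_counts` table (every row a DNA-het site).
#' @param min_depth Minimum ref+alt reads for a site to qualify.
#' @param min_minor_reads Reads required of the lesser-covered allele.
#' @return The concordant fraction in `[0, 1]`, or `NA` (with a warning)
#'   when no site qualifies.
#' @export
dna_rna_het_concordance <- function(counts, min_depth = 8L,
                                    min_minor_reads = 1L) {
  qual <- counts$total_count >= min_depth
  if (!any(qual)) {
    warning("no sites at the required depth; concordance undefined")
    return(NA_real_)
  }
  minor <- pmin(counts$ref_count[qual], counts$alt_count[qual])
  mean(minor >= min_minor_reads)
}
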