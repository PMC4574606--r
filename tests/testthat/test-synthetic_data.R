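# The simulator's own guarantees: determinism, exact bookkeeping against
# the truth table, and agreement of the read-level and counts-level
# generative routes.

test_that("identical config and seed give byte-identical outputs", {
  cfg <- sim_config(n_sites = 15, coverage = 20, error_rate = 0.01,
                    duplicate_rate = 0.3, mate_overlap_fraction = 0.4,
                    reference_bias = 0.9, genotype_error_fraction = 0.1,
                    seed = 55)
  a <- simulate_sample(cfg, dir = tempfile())
  b <- simulate_sample(cfg, dir = tempfile())
  expect_identical(readLines(a$sam), readLines(b$sam))
  expect_identical(readLines(a$vcf), readLines(b$vcf))
  expect_equal(a$truth, b$truth)
})

test_that("read counts in the SAM reconcile exactly with the truth log", {
  cfg <- sim_config(n_sites = 25, coverage = 30, duplicate_rate = 0.25,
                    reference_bias = 0.8, seed = 77)
  s <- simulate_sample(cfg)
  n_reads <- sum(!startsWith(readLines(s$sam), "@"))
  expected_fragments <- sum(s$truth$true_coverage - s$truth$n_bias_dropped +
                              s$truth$n_duplicate_fragments)
  expect_equal(n_reads, 2L * expected_fragments)
})

test_that("dedup removes exactly the injected clones", {
  cfg <- sim_config(n_sites = 20, coverage = 25, duplicate_rate = 0.5,
                    error_rate = 0, seed = 19)
  s <- simulate_sample(cfg)
  on_ <- count_alleles(s$bam, s$sites,
                       counting_options(remove_duplicates = TRUE,
                                        duplicate_detection = "flag",
                                        count_fragments_once = FALSE))
  off <- count_alleles(s$bam, s$sites,
                       counting_options(remove_duplicates = FALSE,
                                        count_fragments_once = FALSE))
  # each fragment has exactly one mate over its site here (no overlap),
  # so every clone adds exactly one counted read
  per_site_clones <- s$truth$n_duplicate_fragments
  expect_equal(off$total_count - on_$total_count, per_site_clones)
  expect_equal(on_$duplicates_dropped, per_site_clones)
})

test_that("clean fixed-coverage runs hit the configured depth and ratio", {
  cfg <- sim_config(n_sites = 100, coverage = 30, error_rate = 0, seed = 3)
  s <- simulate_sample(cfg)
  cts <- count_alleles(s$bam, s$sites,
                       counting_options(remove_duplicates = FALSE))
  expect_true(all(cts$total_count == 30L))
  pooled <- sum(cts$ref_count) / sum(cts$total_count)
  se <- sqrt(0.25 / sum(cts$total_count))
  expect_lt(abs(pooled - 0.5), 3 * se)
})

test_that("reference-bias thinning matches its closed-form expectation", {
  b <- 0.9
  cfg <- sim_config(n_sites = 300, coverage = 60, error_rate = 0,
                    reference_bias = b, seed = 29)
  s <- simulate_sample(cfg)
  cts <- count_alleles(s$bam, s$sites,
                       counting_options(remove_duplicates = FALSE))
  pooled <- sum(cts$ref_count) / sum(cts$total_count)
  expected <- 0.5 / (0.5 + 0.5 * b)   # 10/19
  expect_lt(abs(pooled - expected), 3 * sqrt(0.25 / sum(cts$total_count)) +
              0.005)
})

test_that("the simulated BAM is valid for standard readers", {
  cfg <- sim_config(n_sites = 10, coverage = 10, duplicate_rate = 0.2,
                    mate_overlap_fraction = 0.5, seed = 8)
  s <- simulate_sample(cfg)
  # asBam already validated the SAM; check mate linkage and flags
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "pos", "mpos"))
  reads <- Rsamtools::scanBam(s$bam, param = p)[[1]]
  expect_true(all(bitwAnd(reads$flag, 0x1L) > 0L))   # all paired
  key <- paste(reads$qname, bitwAnd(reads$flag, 0x40L))
  expect_false(any(duplicated(key)))                 # one R1+R2 per fragment
  byfrag <- split(seq_along(reads$qname), reads$qname)
  ok <- vapply(byfrag, function(i)
    length(i) == 2L && all(sort(reads$pos[i]) == sort(reads$mpos[i])),
    logical(1))
  expect_true(all(ok))
})

test_that("counts-level and read-level routes agree statistically", {
  cfg <- sim_config(n_sites = 400, coverage = 40, error_rate = 0.01,
                    reference_bias = 0.9, seed = 47)
  cl <- simulate_counts(cfg)
  s <- simulate_sample(cfg)
  rl <- count_alleles(s$bam, s$sites,
                      counting_options(remove_duplicates = FALSE,
                                       count_fragments_once = FALSE))
  # pooled reference ratios within sampling error of each other
  pr <- function(x) sum(x$ref_count) / sum(x$total_count)
  n <- sum(rl$total_count)
  expect_lt(abs(pr(cl) - pr(rl)), 4 * sqrt(0.5 / n))
  # other-allele rates agree (both ~ 2e/3)
  or <- function(x) sum(x$other_count) / sum(x$raw_depth)
  expect_lt(abs(or(cl) - or(rl)), 4 * sqrt(2 * 0.01 / 3 / n) + 1e-3)
})

test_that("impossible geometry and bad rates are rejected", {
  expect_error(sim_config(read_length = 100, fragment_mean = 80),
               "geometry")
  expect_error(sim_config(error_rate = 0.6), "error_rate")
  expect_error(sim_config(duplicate_rate = 1.2), "duplicate_rate")
})

test_that("cohort simulation assigns genotypes and effects per gene", {
  base <- sim_config(coverage = 40, error_rate = 0, seed = 1)
  co <- simulate_cohort(base, n_individuals = 4, n_egenes = 5,
                        het_effect = 0.3, cohort_seed = 9,
                        sites_per_gene = 2)
  expect_length(co$samples, 4L)
  expect_equal(nrow(co$esnp_genotypes), 20L)
  # het individuals carry the shifted true ratio at that gene's sites
  ind <- co$samples[[1]]
  gt <- co$esnp_genotypes[co$esnp_genotypes$individual_id == ind$name, ]
  for (g in seq_len(5)) {
    rows <- ind$truth[(2 * g - 1):(2 * g), ]
    if (gt$esnp_genotype[g] == "heterozygous")
      expect_equal(abs(rows$true_ref_ratio - 0.5), rep(0.3, 2))
    else expect_equal(rows$true_ref_ratio, rep(0.5, 2))
  }
  # all individuals share one site universe
  expect_equal(co$samples[[1]]$sites, co$samples[[4]]$sites)
})
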