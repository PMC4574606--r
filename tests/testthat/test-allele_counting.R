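# Counting semantics against hand-enumerated and brute-force oracles.

test_that("hand-built 20-read pileup matches its manual enumeration", {
  fx <- hand_sam_fixture()
  cts <- count_alleles(fx$bam, fx$site, counting_options(rng_seed = 42))
  e <- HAND_SAM_EXPECTED
  expect_equal(cts$ref_count, e$ref)
  expect_equal(cts$alt_count, e$alt)
  expect_equal(cts$other_count, e$other)
  expect_equal(cts$total_count, e$total)
  expect_equal(cts$raw_depth, e$raw_depth)
  expect_equal(cts$low_baseq_dropped, e$low_baseq)
  expect_equal(cts$low_mapq_dropped, e$low_mapq)
  expect_equal(cts$duplicates_dropped, e$dups)
  expect_equal(cts$mate_conflicts_dropped, e$conflicts)
  expect_equal(cts$overlapping_mates_merged, e$merged)
  expect_equal(cts$improper_pairs, e$improper)
  expect_true(conservation_holds(cts))
})

test_that("with dedup and mate merging off, counts equal an independent
           naive SAM tally", {
  fx <- hand_sam_fixture()
  opt <- counting_options(remove_duplicates = FALSE,
                          count_fragments_once = FALSE)
  cts <- count_alleles(fx$bam, fx$site, opt)
  oracle <- naive_sam_tally(fx$sam, "chr1", 100, "A", "G",
                            min_bq = opt$min_base_quality,
                            min_mq = opt$min_mapping_quality)
  expect_equal(cts$ref_count, unname(oracle["ref"]))
  expect_equal(cts$alt_count, unname(oracle["alt"]))
  expect_equal(cts$other_count, unname(oracle["other"]))
  expect_equal(cts$raw_depth, unname(oracle["with_base"]))

  # and on simulator output with all artifacts disabled
  cfg <- sim_config(n_sites = 8, coverage = 25, error_rate = 0.02, seed = 11)
  s <- simulate_sample(cfg)
  cts2 <- count_alleles(s$bam, s$sites, opt)
  for (i in seq_len(nrow(cts2))) {
    orc <- naive_sam_tally(s$sam, cts2$chrom[i], cts2$pos[i],
                           cts2$ref[i], cts2$alt[i],
                           min_bq = opt$min_base_quality,
                           min_mq = opt$min_mapping_quality)
    expect_equal(cts2$ref_count[i], unname(orc["ref"]))
    expect_equal(cts2$alt_count[i], unname(orc["alt"]))
    expect_equal(cts2$other_count[i], unname(orc["other"]))
  }
})

test_that("raising quality thresholds never increases allele counts", {
  fx <- hand_sam_fixture()
  base <- count_alleles(fx$bam, fx$site,
                        counting_options(min_base_quality = 0,
                                         min_mapping_quality = 0))
  for (bq in c(10, 41)) for (mq in c(20, 61)) {
    cts <- count_alleles(fx$bam, fx$site,
                         counting_options(min_base_quality = bq,
                                          min_mapping_quality = mq))
    expect_lte(cts$ref_count, base$ref_count)
    expect_lte(cts$alt_count, base$alt_count)
    expect_lte(cts$other_count, base$other_count)
    expect_true(conservation_holds(cts))
  }
})

test_that("min_depth omits shallow sites; zero-coverage sites are kept
           at min_depth 0", {
  cfg <- sim_config(n_sites = 10, coverage = 5, coverage_dispersion = 0.5,
                    seed = 3)
  s <- simulate_sample(cfg)
  all_sites <- count_alleles(s$bam, s$sites, counting_options(min_depth = 0))
  expect_equal(nrow(all_sites), 10L)
  deep <- count_alleles(s$bam, s$sites, counting_options(min_depth = 4))
  expect_true(all(deep$total_count >= 4))
  expect_equal(nrow(deep), sum(all_sites$total_count >= 4))
})

test_that("unknown chromosomes and missing indexes are refused", {
  fx <- hand_sam_fixture()
  bad <- het_sites("chrMISSING", 100L, "A", "G")
  expect_error(count_alleles(fx$bam, bad), "chrMISSING")
  noidx <- tempfile(fileext = ".bam")
  file.copy(fx$bam, noidx)
  expect_error(count_alleles(noidx, fx$site), "indexed")
})

test_that("fragment-overlap resolution counts consistent mates once at
           the higher quality and discards conflicts", {
  expect_equal(resolve_fragment_overlap("A", 30, "A", 20),
               list(base = "A", qual = 30))
  expect_null(resolve_fragment_overlap("A", 30, "G", 30))
  # max-quality rule at the threshold boundary
  r <- resolve_fragment_overlap("A", 30, "A", 5)
  expect_equal(r$qual, 30)
  expect_gte(r$qual, 10)
})

test_that("fragment-once counting halves totals when every site is
           covered by both agreeing mates", {
  cfg <- sim_config(n_sites = 12, coverage = 20, mate_overlap_fraction = 1,
                    error_rate = 0, seed = 5)
  s <- simulate_sample(cfg)
  once <- count_alleles(s$bam, s$sites,
                        counting_options(count_fragments_once = TRUE,
                                         remove_duplicates = FALSE))
  twice <- count_alleles(s$bam, s$sites,
                         counting_options(count_fragments_once = FALSE,
                                          remove_duplicates = FALSE))
  expect_equal(2L * once$total_count, twice$total_count)
})

test_that("duplicate representative selection is policy-faithful", {
  # singleton: returned regardless of policy
  expect_equal(select_duplicate_representative(30, "random"), 1L)
  expect_equal(select_duplicate_representative(30, "by_base_quality"), 1L)
  # argmax under by_base_quality
  expect_equal(select_duplicate_representative(c(40, 20, 10),
                                               "by_base_quality"), 1L)
  expect_equal(select_duplicate_representative(c(10, 20, 40),
                                               "by_base_quality"), 3L)
  # reproducible under seed
  expect_equal(select_duplicate_representative(c(10, 10, 10), "random",
                                               seed = 9),
               select_duplicate_representative(c(10, 10, 10), "random",
                                               seed = 9))
  expect_error(select_duplicate_representative(numeric(0), "random"),
               "non-empty")
})

test_that("random dedup retains REF at the group REF frequency", {
  # group of 2 carrying REF and ALT; uniform retention = 50 %
  picks <- vapply(1:4000, function(s)
    select_duplicate_representative(c(30, 30), "random", seed = s),
    integer(1))
  f <- mean(picks == 1L)
  expect_gt(f, 0.5 - 3 * sqrt(0.25 / 4000))
  expect_lt(f, 0.5 + 3 * sqrt(0.25 / 4000))
})

test_that("counts tables round-trip losslessly with the GATK-style
           column order", {
  cfg <- sim_config(n_sites = 50, coverage = 30, error_rate = 0.01,
                    duplicate_rate = 0.2, mate_overlap_fraction = 0.3,
                    seed = 21)
  s <- simulate_sample(cfg)
  cts <- count_alleles(s$bam, s$sites)
  path <- tempfile(fileext = ".tsv")
  write_counts_table(cts, path)
  hdr <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  expect_identical(hdr[1:13],
                   c("contig", "position", "variantID", "refAllele",
                     "altAllele", "refCount", "altCount", "totalCount",
                     "lowMAPQDepth", "lowBaseQDepth", "rawDepth",
                     "otherBases", "improperPairs"))
  back <- read_counts_table(path)
  expect_equal(as.data.frame(back), as.data.frame(cts))

  empty <- tempfile(fileext = ".tsv")
  write_counts_table(cts[0, ], empty)
  expect_equal(nrow(read_counts_table(empty)), 0L)
})

test_that("counting is deterministic under the rng seed", {
  cfg <- sim_config(n_sites = 20, coverage = 25, duplicate_rate = 0.4,
                    seed = 13)
  s <- simulate_sample(cfg)
  opt <- counting_options(duplicate_policy = "random",
                          duplicate_detection = "signature", rng_seed = 99)
  a <- count_alleles(s$bam, s$sites, opt)
  b <- count_alleles(s$bam, s$sites, opt)
  expect_equal(a, b)
})

test_that("counting options forbid mapping-score duplicate selection", {
  expect_error(counting_options(duplicate_policy = "by_mapping_score"))
})
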