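# Read-level simulator with known truth.
#
# Emulates the error sources an AE pipeline must handle — sequencing
# noise, PCR duplicates, overlapping mate pairs, genotyping errors
# (truly homozygous sites in the "het" list) and reference mapping bias
# (thinning of ALT-carrying reads) — while recording the generative
# truth per site, so parameter recovery is testable end to end.
#
# Geometry is stylized for exact bookkeeping: sites are spaced so no
# fragment covers two sites; fragments flagged as mate-overlapping get
# an insert shorter than two read lengths with the site inside the
# overlap, all others get an insert of at least two read lengths, so the
# configured mate_overlap_fraction is exact by construction.

.BASES <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' @param n_sites Number of het-SNP sites.
#' @param coverage Mean fragment coverage per site.
#' @param coverage_dispersion Negative-binomial size parameter for
#'   per-site coverage; `Inf` gives fixed coverage.
#' @param ref_ratio True reference-allele ratio at het sites: a scalar,
#'   or a vector of per-site values (length `n_sites`).
#' @param ratio_spread Overdispersion of true ratios: when `> 0`,
#'   per-site ratios are drawn from a Beta distribution with mean
#'   `ref_ratio` and concentration `1 / ratio_spread`.
#' @param shared_ratios Draw the per-site true ratios under
#'   `sites_seed` instead of `seed`, so samples sharing a site universe
#'   also share true allelic ratios (population-shared AE, e.g.
#'   eQTL-driven).
#' @param error_rate Per-base substitution rate; errors are uniform
#'   over the three non-template bases. Must be `< 0.5`.
#' @param duplicate_rate Probability a sequenced fragment is PCR-cloned
#'   once; clones share coordinates and allele, carry the SAM duplicate
#'   flag, and get independent sequencing errors.
#' @param mate_overlap_fraction Fraction of fragments whose two mates
#'   both cover their site.
#' @param genotype_error_fraction Fraction of "het" sites that are truly
#'   homozygous (the genotyping-error model); the VCF still calls them
#'   het.
#' @param reference_bias Retention probability of an ALT-carrying
#'   fragment (1 = unbiased); models allelic mapping bias as thinning.
#' @param read_length,fragment_mean,fragment_sd Read/fragment geometry
#'   in bp; `fragment_mean` must be at least `read_length`.
#' @param seed Seed for everything sample-specific (genotypes, reads,
#'   errors).
#' @param sites_seed Seed for the site universe (positions, REF/ALT
#'   alleles, and shared ratios); samples with equal `n_sites`,
#'   geometry and `sites_seed` share their sites.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_sites = 100L, coverage = 30, coverage_dispersion = Inf,
                       ref_ratio = 0.5, ratio_spread = 0,
                       shared_ratios = FALSE,
                       error_rate = 0.001, duplicate_rate = 0,
                       mate_overlap_fraction = 0,
                       genotype_error_fraction = 0,
                       reference_bias = 1,
                       read_length = 50L, fragment_mean = 150,
                       fragment_sd = 20, seed = 1L, sites_seed = 1L) {
  chk01 <- function(x, nm) if (any(x < 0) || any(x > 1))
    stop(nm, " must be in [0, 1]")
  chk01(ref_ratio, "ref_ratio"); chk01(duplicate_rate, "duplicate_rate")
  chk01(mate_overlap_fraction, "mate_overlap_fraction")
  chk01(genotype_error_fraction, "genotype_error_fraction")
  chk01(reference_bias, "reference_bias")
  if (error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must be in [0, 0.5)")
  if (!(length(ref_ratio) %in% c(1L, n_sites)))
    stop("ref_ratio must be a scalar or one value per site")
  if (fragment_mean < read_length)
    stop("fragment_mean shorter than read_length: impossible geometry")
  structure(list(n_sites = as.integer(n_sites), coverage = coverage,
                 coverage_dispersion = coverage_dispersion,
                 ref_ratio = ref_ratio, ratio_spread = ratio_spread,
                 shared_ratios = isTRUE(shared_ratios),
                 error_rate = error_rate, duplicate_rate = duplicate_rate,
                 mate_overlap_fraction = mate_overlap_fraction,
                 genotype_error_fraction = genotype_error_fraction,
                 reference_bias = reference_bias,
                 read_length = as.integer(read_length),
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 seed = as.integer(seed), sites_seed = as.integer(sites_seed)),
            class = "sim_config")
}

# Largest fragment the simulator will emit.
.frag_cap <- function(config) {
  max(2L * config$read_length,
      ceiling(config$fragment_mean + 6 * config$fragment_sd))
}

# Deterministic site layout: positions spaced beyond any fragment span.
.site_positions <- function(config) {
  cap <- .frag_cap(config)
  spacing <- 2L * cap + 200L
  offset <- cap + config$read_length + 100L
  as.integer(offset + (seq_len(config$n_sites) - 1L) * spacing)
}

# The site universe (positions, alleles, optionally shared true ratios)
# depends only on sites_seed + geometry.
.site_universe <- function(config) {
  pos <- .site_positions(config)
  .with_seed(config$sites_seed, {
    ref <- sample(.BASES, config$n_sites, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(.BASES, b), 1L), "")
    shared_ratio <- if (config$shared_ratios)
      .draw_ratios(config) else NULL
    list(sites = het_sites("chr1", pos, ref, alt,
                           site_id = sprintf("site%04d", seq_along(pos))),
         shared_ratio = shared_ratio)
  })
}

.draw_ratios <- function(config) {
  r <- rep_len(config$ref_ratio, config$n_sites)
  if (config$ratio_spread > 0) {
    kappa <- 1 / config$ratio_spread
    r <- rbeta(config$n_sites, r * kappa, (1 - r) * kappa)
    r <- pmin(pmax(r, 1e-6), 1 - 1e-6)
  }
  r
}

#' Simulate one RNA-seq sample over a het-SNP universe
#'
#' Writes a coordinate-sorted, indexed BAM (via an intermediate SAM), a
#' VCF calling every site heterozygous (including the injected
#' genotyping errors), and a truth table, all under `dir`. Identical
#' config and seed give identical output.
#'
#' @param config A [sim_config].
#' @param dir Output directory (created if needed).
#' @param name Sample name used in file names and the VCF.
#' @return A list with paths `sam`, `bam`, `vcf`, `truth_path`, the
#'   [het_sites] table `sites`, and the truth `data.frame` `truth`
#'   (columns `chrom, pos, site_id, ref, alt, true_genotype,
#'   true_ref_ratio, true_coverage, n_bias_dropped,
#'   n_duplicate_fragments, n_overlap_fragments`).
#' @export
simulate_sample <- function(config, dir = tempfile("aeqc_sim"),
                            name = "sample") {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  uni <- .site_universe(config)
  sites <- uni$sites
  L <- config$read_length
  cap <- .frag_cap(config)
  qual_chars <- 25:40 + 33L

  out <- .with_seed(config$seed, {
    n <- config$n_sites
    genotype <- ifelse(runif(n) < config$genotype_error_fraction,
                       ifelse(runif(n) < 0.5, "hom_ref", "hom_alt"), "het")
    ratio <- if (!is.null(uni$shared_ratio)) uni$shared_ratio
             else .draw_ratios(config)
    ratio[genotype == "hom_ref"] <- 1
    ratio[genotype == "hom_alt"] <- 0
    cov <- if (is.finite(config$coverage_dispersion))
      rnbinom(n, mu = config$coverage, size = config$coverage_dispersion)
    else rep(as.integer(round(config$coverage)), n)

    recs <- vector("list", n)
    truth <- data.frame(as.data.frame(sites),
                        true_genotype = genotype, true_ref_ratio = ratio,
                        true_coverage = as.integer(cov),
                        n_bias_dropped = 0L, n_duplicate_fragments = 0L,
                        n_overlap_fragments = 0L, stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      s <- .sim_site_reads(i, sites[i, ], ratio[i], cov[i], config, L, cap,
                           qual_chars)
      truth$n_bias_dropped[i] <- s$n_bias_dropped
      truth$n_duplicate_fragments[i] <- s$n_dup
      truth$n_overlap_fragments[i] <- s$n_overlap
      recs[[i]] <- s$reads
    }
    list(reads = do.call(rbind, recs), truth = truth)
  })

  sam_path <- file.path(dir, paste0(name, ".sam"))
  vcf_path <- file.path(dir, paste0(name, ".vcf"))
  truth_path <- file.path(dir, paste0(name, ".truth.tsv"))
  chrom_len <- max(sites$pos) + 2L * cap + 2000L
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              paste0("@SQ\tSN:chr1\tLN:", chrom_len))
  reads <- out$reads
  if (!is.null(reads) && nrow(reads) > 0L) {
    reads <- reads[order(reads$pos), , drop = FALSE]
    lines <- paste(reads$qname, reads$flag, "chr1", reads$pos, reads$mapq,
                   reads$cigar, "=", reads$pnext, reads$tlen, reads$seq,
                   reads$qual, sep = "\t")
  } else lines <- character()
  writeLines(c(header, lines), sam_path)
  bam_path <- suppressMessages(Rsamtools::asBam(
    sam_path, destination = file.path(dir, name), overwrite = TRUE,
    indexDestination = TRUE))

  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                      name),
               paste(sites$chrom, sites$pos, sites$site_id, sites$ref,
                     sites$alt, ".", "PASS", ".", "GT", "0/1", sep = "\t")),
             vcf_path)
  write.table(out$truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(sam = sam_path, bam = bam_path, vcf = vcf_path,
       truth_path = truth_path, sites = sites, truth = out$truth,
       config = config, name = name)
}

# Reads for one site; returns a data.frame of SAM fields plus truth
# tallies. Consumes the ambient RNG stream.
.sim_site_reads <- function(i, site, ratio, cov, config, L, cap, qual_chars) {
  P <- site$pos
  empty <- list(reads = NULL, n_bias_dropped = 0L, n_dup = 0L,
                n_overlap = 0L)
  if (cov == 0L) return(empty)
  is_ref <- runif(cov) < ratio
  # reference mapping bias: ALT fragments fail to align w.p. 1 - bias
  drop <- !is_ref & runif(cov) >= config$reference_bias
  n_bias_dropped <- sum(drop)
  is_ref <- is_ref[!drop]
  m <- length(is_ref)
  if (m == 0L)
    return(list(reads = NULL, n_bias_dropped = n_bias_dropped,
                n_dup = 0L, n_overlap = 0L))
  overlap <- runif(m) < config$mate_overlap_fraction
  frag <- integer(m)
  frag[overlap] <- L + max(1L, L %/% 2L)
  if (any(!overlap)) {
    f <- round(rnorm(sum(!overlap), config$fragment_mean, config$fragment_sd))
    frag[!overlap] <- pmin(pmax(f, 2L * L), cap)
  }
  start <- integer(m)
  if (any(overlap)) {        # site inside the mate-overlap region
    lo <- P - L + 1L; hi <- P - frag[overlap] + L
    start[overlap] <- lo + floor(runif(sum(overlap)) * (hi - lo + 1L))
  }
  if (any(!overlap)) {       # site covered by exactly one mate
    no <- which(!overlap)
    first <- runif(length(no)) < 0.5
    s1 <- P - L + 1L + floor(runif(length(no)) * L)  # mate covering P
    start[no] <- ifelse(first, s1, s1 - frag[no] + L)
  }
  dup <- runif(m) < config$duplicate_rate
  n_dup <- sum(dup)

  # local reference segment around the site, REF allele planted
  seg_start <- P - cap - L - 10L
  seg <- paste(sample(.BASES, 2L * (cap + L + 10L) + 1L, replace = TRUE),
               collapse = "")
  substr(seg, P - seg_start + 1L, P - seg_start + 1L) <- site$ref

  ord <- c(seq_len(m), which(dup))           # clones appended
  is_clone <- c(rep(FALSE, m), rep(TRUE, n_dup))
  fstart <- start[ord]; ffrag <- frag[ord]; fref <- is_ref[ord]
  qname <- sprintf("frag_s%04d_%03d%s", i, ord,
                   ifelse(is_clone, "_dup", ""))
  nf <- length(ord)

  pos1 <- fstart; pos2 <- fstart + ffrag - L
  allele <- ifelse(fref, site$ref, site$alt)
  mk_read <- function(rpos) {
    sq <- substring(seg, rpos - seg_start + 1L, rpos - seg_start + L)
    covers <- rpos <= P & P <= rpos + L - 1L
    off <- P - rpos + 1L
    idx <- which(covers)
    for (j in idx) substr(sq[j], off[j], off[j]) <- allele[j]
    # sequencing errors, uniform over the three non-template bases
    err <- which(runif(nf * L) < config$error_rate)
    for (e in err) {
      r <- (e - 1L) %/% L + 1L; p <- (e - 1L) %% L + 1L
      cur <- substr(sq[r], p, p)
      substr(sq[r], p, p) <- sample(setdiff(.BASES, cur), 1L)
    }
    ql <- vapply(seq_len(nf), function(j)
      intToUtf8(sample(qual_chars, L, replace = TRUE)), "")
    list(seq = sq, qual = ql)
  }
  r1 <- mk_read(pos1); r2 <- mk_read(pos2)
  flag1 <- 99L + ifelse(is_clone, 1024L, 0L)   # paired,proper,mate-rev,first
  flag2 <- 147L + ifelse(is_clone, 1024L, 0L)  # paired,proper,rev,second
  list(reads = data.frame(
         qname = c(qname, qname), flag = c(flag1, flag2),
         pos = c(pos1, pos2), mapq = 60L,
         cigar = paste0(L, "M"), pnext = c(pos2, pos1),
         tlen = c(ffrag, -ffrag), seq = c(r1$seq, r2$seq),
         qual = c(r1$qual, r2$qual), stringsAsFactors = FALSE),
       n_bias_dropped = n_bias_dropped, n_dup = n_dup,
       n_overlap = sum(overlap))
}

#' Simulate allele counts directly (counts-level twin)
#'
#' Draws per-site counts from the same observation model as
#' [simulate_sample()] — fragment alleles at the true ratio, ALT
#' thinning at `1 - reference_bias`, then per-read substitution errors
#' uniform over the three non-template bases — without constructing
#' reads. Used for large calibration experiments; agreement of the two
#' routes is part of the test suite. Duplicate and mate-overlap knobs do
#' not apply at this level.
#'
#' @param config A [sim_config].
#' @return A `site_counts` table with attribute `truth`.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  uni <- .site_universe(config)
  sites <- uni$sites
  .with_seed(config$seed, {
    n <- config$n_sites
    genotype <- ifelse(runif(n) < config$genotype_error_fraction,
                       ifelse(runif(n) < 0.5, "hom_ref", "hom_alt"), "het")
    ratio <- if (!is.null(uni$shared_ratio)) uni$shared_ratio
             else .draw_ratios(config)
    ratio[genotype == "hom_ref"] <- 1
    ratio[genotype == "hom_alt"] <- 0
    cov <- if (is.finite(config$coverage_dispersion))
      rnbinom(n, mu = config$coverage, size = config$coverage_dispersion)
    else rep(as.integer(round(config$coverage)), n)
    nref <- rbinom(n, cov, ratio)
    nalt <- rbinom(n, cov - nref, config$reference_bias)
    e <- config$error_rate
    # errors off REF reads
    eref <- rbinom(n, nref, e); ref_to_alt <- rbinom(n, eref, 1 / 3)
    # errors off ALT reads
    ealt <- rbinom(n, nalt, e); alt_to_ref <- rbinom(n, ealt, 1 / 3)
    ref_obs <- nref - eref + alt_to_ref
    alt_obs <- nalt - ealt + ref_to_alt
    other_obs <- (eref - ref_to_alt) + (ealt - alt_to_ref)
    out <- data.frame(as.data.frame(sites),
                      ref_count = ref_obs, alt_count = alt_obs,
                      other_count = other_obs,
                      total_count = ref_obs + alt_obs,
                      raw_depth = ref_obs + alt_obs + other_obs,
                      low_baseq_dropped = 0L, low_mapq_dropped = 0L,
                      duplicates_dropped = 0L, mate_conflicts_dropped = 0L,
                      overlapping_mates_merged = 0L, improper_pairs = 0L,
                      stringsAsFactors = FALSE)
    class(out) <- c("site_counts", "data.frame")
    attr(out, "truth") <- data.frame(as.data.frame(sites),
                                     true_genotype = genotype,
                                     true_ref_ratio = ratio,
                                     true_coverage = as.integer(cov),
                                     stringsAsFactors = FALSE)
    out
  })
}

#' Simulate a cohort with eQTL-driven allelic expression
#'
#' Lays `n_egenes` genes over the site universe (consecutive blocks of
#' `sites_per_gene` sites), assigns each individual a heterozygous or
#' homozygous genotype at each gene's eSNP (probability 1/2 each), and
#' gives eSNP-heterozygous individuals a true allelic ratio of
#' `0.5 +/- het_effect` (random sign per site) at that gene's sites;
#' homozygous individuals stay at 0.5. All other knobs come from
#' `base`. Each individual is a full [simulate_sample()] run.
#'
#' @param base A [sim_config]; its `n_sites` is overridden by
#'   `n_egenes * sites_per_gene` and its `ref_ratio`/`seed` per
#'   individual.
#' @param n_individuals Number of individuals.
#' @param n_egenes Number of eGenes.
#' @param het_effect True AE effect size in heterozygotes, in
#'   `[0, 0.5)`.
#' @param cohort_seed Seed for genotype assignment and per-individual
#'   seeds.
#' @param sites_per_gene Het-SNPs per gene.
#' @param dir Output directory.
#' @return A list with `samples` (named list of sample bundles),
#'   `esnp_genotypes` (`individual_id`, `gene_id`, `esnp_genotype`),
#'   `genes` (`gene_id`, `chrom`, `start`, `end`).
#' @export
simulate_cohort <- function(base, n_individuals, n_egenes,
                            het_effect = 0.25, cohort_seed = 1L,
                            sites_per_gene = 2L,
                            dir = tempfile("aeqc_cohort")) {
  stopifnot(inherits(base, "sim_config"), het_effect >= 0, het_effect < 0.5)
  n_sites <- n_egenes * sites_per_gene
  proto <- base
  proto$n_sites <- as.integer(n_sites)
  proto$ref_ratio <- 0.5
  uni <- .site_universe(proto)
  pos <- uni$sites$pos
  gene_of_site <- rep(seq_len(n_egenes), each = sites_per_gene)
  genes <- data.frame(
    gene_id = sprintf("gene%03d", seq_len(n_egenes)), chrom = "chr1",
    start = tapply(pos, gene_of_site, min) - 10L,
    end = tapply(pos, gene_of_site, max) + 10L, stringsAsFactors = FALSE)

  plan <- .with_seed(cohort_seed, {
    gt <- matrix(ifelse(runif(n_individuals * n_egenes) < 0.5,
                        "heterozygous", "homozygous"),
                 nrow = n_individuals)
    signs <- matrix(sample(c(-1, 1), n_individuals * n_sites, replace = TRUE),
                    nrow = n_individuals)
    seeds <- sample.int(1e8L, n_individuals)
    list(gt = gt, signs = signs, seeds = seeds)
  })

  samples <- vector("list", n_individuals)
  ids <- sprintf("ind%03d", seq_len(n_individuals))
  esnp <- NULL
  for (k in seq_len(n_individuals)) {
    het_gene <- plan$gt[k, gene_of_site] == "heterozygous"
    ratios <- rep(0.5, n_sites)
    ratios[het_gene] <- 0.5 + plan$signs[k, het_gene] * het_effect
    cfg <- proto
    cfg$ref_ratio <- ratios
    cfg$seed <- plan$seeds[k]
    samples[[k]] <- simulate_sample(cfg, dir = file.path(dir, ids[k]),
                                    name = ids[k])
    esnp <- rbind(esnp, data.frame(individual_id = ids[k],
                                   gene_id = genes$gene_id,
                                   esnp_genotype = plan$gt[k, ],
                                   stringsAsFactors = FALSE))
  }
  names(samples) <- ids
  list(samples = samples, esnp_genotypes = esnp, genes = genes,
       sites = uni$sites)
}
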