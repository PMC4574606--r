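# Independent oracles: deliberately separate implementations used to
# cross-check package results.

# Brute-force pileup over SAM text. Re-implements base extraction from
# scratch (own cigar walk, own flag logic); applies only the quality
# thresholds -- no deduplication or mate merging, so it matches
# count_alleles when those are disabled.
naive_sam_tally <- function(sam_path, chrom, pos, ref, alt,
                            min_bq = 10, min_mq = 20) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  counts <- c(ref = 0L, alt = 0L, other = 0L, low_bq = 0L, low_mq = 0L,
              with_base = 0L)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0L) next                   # unmapped
    if (bitwAnd(flag, 256L) > 0L || bitwAnd(flag, 2048L) > 0L) next
    if (f[3] != chrom) next
    rpos <- as.integer(f[4]); cig <- f[6]
    # independent cigar walk
    lens <- as.integer(strsplit(gsub("[MIDNSHP=X]", " ", cig), " ")[[1]])
    ops <- strsplit(gsub("[0-9]+", "", cig), "")[[1]]
    qoff <- NA_integer_; q <- 1L; r <- rpos
    for (k in seq_along(ops)) {
      if (ops[k] %in% c("M", "=", "X")) {
        if (pos >= r && pos <= r + lens[k] - 1L) { qoff <- q + pos - r; break }
        q <- q + lens[k]; r <- r + lens[k]
      } else if (ops[k] %in% c("D", "N")) {
        if (pos >= r && pos <= r + lens[k] - 1L) break
        r <- r + lens[k]
      } else if (ops[k] %in% c("I", "S")) q <- q + lens[k]
    }
    if (is.na(qoff)) next
    counts["with_base"] <- counts["with_base"] + 1L
    if (as.integer(f[5]) < min_mq) { counts["low_mq"] <- counts["low_mq"] + 1L; next }
    b <- toupper(substr(f[10], qoff, qoff))
    bq <- utf8ToInt(substr(f[11], qoff, qoff)) - 33L
    if (bq < min_bq) { counts["low_bq"] <- counts["low_bq"] + 1L; next }
    if (b == ref) counts["ref"] <- counts["ref"] + 1L
    else if (b == alt) counts["alt"] <- counts["alt"] + 1L
    else counts["other"] <- counts["other"] + 1L
  }
  counts
}

# Brute-force tail sum for the homozygosity test: explicit term-by-term
# summation of binomial probability masses.
brute_hom_p <- function(n_R, n_A, eps) {
  n <- n_R + n_A
  mass <- function(k) choose(n, k) * eps^k * (1 - eps)^(n - k)
  tail_from <- function(k0) {
    if (k0 > n) return(0)
    if (k0 <= 0) return(1)
    sum(vapply(k0:n, mass, numeric(1)))
  }
  min(1, tail_from(n_A) + tail_from(n_R))
}

# Brute-force two-sided binomial p-value at null 0.5: doubled smaller
# tail, term-by-term.
brute_binom_p_half <- function(r, n) {
  mass <- function(k) choose(n, k) * 0.5^n
  lower <- sum(vapply(0:r, mass, numeric(1)))
  upper <- sum(vapply(r:n, mass, numeric(1)))
  min(1, 2 * min(lower, upper))
}

# Sensitivity of the homozygosity flag at fixed coverage/epsilon: the
# binomial power of observing few enough minor-allele reads that the
# two-tail sum stays above the rejection threshold. Computed by direct
# enumeration over the minor count distribution under true homozygosity
# (minor reads arise at rate eps_true_minor).
hom_flag_power <- function(n, eps_test, eps_true_minor, p_threshold) {
  # site truly hom_ref: n_A ~ Binomial(n, eps_true_minor)
  p_flag <- 0
  for (na in 0:n) {
    p_site <- homozygosity_test(n - na, na, eps_test)
    if (p_site > p_threshold)
      p_flag <- p_flag + dbinom(na, n, eps_true_minor)
  }
  p_flag
}
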