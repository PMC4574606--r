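# Filtered allele counting at het-SNPs from coordinate-sorted alignments.
#
# Counting semantics: at each site every primary alignment with an
# aligned base over the position is accounted for exactly once, either in
# an allele tally (ref/alt/other) or in one of the filter tallies
# (low mapq, duplicates, mate conflicts, merged mates, low base quality),
# so ref + alt + other + all filter tallies == raw_depth at every site.

#' Options controlling allele counting
#'
#' @param min_base_quality Minimum Phred base quality at the site for a
#'   read to be counted (after mate-overlap merging, which uses the
#'   higher of the two mate qualities).
#' @param min_mapping_quality Minimum mapping quality; together with the
#'   exclusion of secondary/supplementary alignments this enforces
#'   unique mapping.
#' @param remove_duplicates Drop duplicate reads, keeping one
#'   representative per duplicate group.
#' @param duplicate_policy How the retained duplicate is chosen:
#'   `"random"` (uniform) or `"by_base_quality"` (highest base quality at
#'   the site, ties broken randomly). Selection by mapping score is
#'   deliberately not offered: it would bias retention towards
#'   reference-allele reads.
#' @param duplicate_detection `"flag"` trusts the SAM duplicate flag
#'   (0x400), `"signature"` groups reads by (strand, unclipped start,
#'   mate start), `"auto"` uses the flag when any read in the file
#'   carries it and falls back to signatures otherwise.
#' @param count_fragments_once Count a read pair whose mates both cover
#'   the site once per fragment; discordant mate base calls discard the
#'   fragment.
#' @param min_depth Sites with fewer than this many counted (ref+alt)
#'   reads are omitted from the output; 0 keeps every site.
#' @param rng_seed Seed making random duplicate selection reproducible.
#' @return A list of class `"counting_options"`.
#' @export
counting_options <- function(min_base_quality = 10L,
                             min_mapping_quality = 20L,
                             remove_duplicates = TRUE,
                             duplicate_policy = c("random", "by_base_quality"),
                             duplicate_detection = c("auto", "flag", "signature"),
                             count_fragments_once = TRUE,
                             min_depth = 0L,
                             rng_seed = 1L) {
  duplicate_policy <- match.arg(duplicate_policy)
  duplicate_detection <- match.arg(duplicate_detection)
  stopifnot(min_base_quality >= 0, min_mapping_quality >= 0, min_depth >= 0)
  structure(list(min_base_quality = as.integer(min_base_quality),
                 min_mapping_quality = as.integer(min_mapping_quality),
                 remove_duplicates = isTRUE(remove_duplicates),
                 duplicate_policy = duplicate_policy,
                 duplicate_detection = duplicate_detection,
                 count_fragments_once = isTRUE(count_fragments_once),
                 min_depth = as.integer(min_depth),
                 rng_seed = as.integer(rng_seed)),
            class = "counting_options")
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

# 1-based offset into SEQ of the base aligned over `target`, or NA when
# the alignment covers the position with a deletion/splice gap or not at
# all. Fast path for gapless "<n>M" cigars.
.query_offset <- function(pos, cigar, target) {
  n <- length(pos)
  off <- rep(NA_integer_, n)
  plain <- grepl("^[0-9]+M$", cigar)
  off[plain] <- target - pos[plain] + 1L
  len_plain <- as.integer(sub("M", "", cigar[plain], fixed = TRUE))
  off[plain][off[plain] < 1L | off[plain] > len_plain] <- NA_integer_
  for (i in which(!plain)) {
    lens <- as.integer(regmatches(cigar[i], gregexpr("[0-9]+", cigar[i]))[[1]])
    ops <- regmatches(cigar[i], gregexpr("[A-Z=]", cigar[i]))[[1]]
    rpos <- pos[i]; qpos <- 1L
    for (j in seq_along(ops)) {
      op <- ops[j]; l <- lens[j]
      if (op %in% c("M", "=", "X")) {
        if (target >= rpos && target < rpos + l) {
          off[i] <- qpos + (target - rpos)
          break
        }
        rpos <- rpos + l; qpos <- qpos + l
      } else if (op %in% c("D", "N")) {
        if (target >= rpos && target < rpos + l) break  # gap over site
        rpos <- rpos + l
      } else if (op %in% c("I", "S")) {
        qpos <- qpos + l
      }                                 # H, P consume neither
    }
  }
  off
}

.leading_clip <- function(cigar) {
  out <- integer(length(cigar))
  idx <- grepl("^[0-9]+[SH]", cigar)
  out[idx] <- as.integer(sub("^([0-9]+)[SH].*", "\\1", cigar[idx]))
  out
}

#' Choose the retained read from a duplicate group
#'
#' Exactly one read of a duplicate group is kept; the choice is uniform
#' (`"random"`) or the read with the highest base quality at the site
#' (`"by_base_quality"`, ties broken uniformly). Mapping quality is never
#' consulted, so retention cannot systematically favour reference-allele
#' reads (which tend to have higher mapping scores).
#'
#' @param base_quals Phred base qualities at the site, one per read in
#'   the group.
#' @param policy `"random"` or `"by_base_quality"`.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return The index of the retained read.
#' @export
select_duplicate_representative <- function(base_quals,
                                            policy = c("random", "by_base_quality"),
                                            seed = NULL) {
  policy <- match.arg(policy)
  n <- length(base_quals)
  if (n == 0L) stop("duplicate group must be non-empty")
  pick <- function() {
    if (n == 1L) return(1L)
    if (policy == "random") {
      sample.int(n, 1L)
    } else {
      cand <- which(base_quals == max(base_quals))
      if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
    }
  }
  if (is.null(seed)) pick() else .with_seed(seed, pick())
}

#' Resolve the base call of a fragment whose mates overlap a site
#'
#' Each sequenced fragment represents one RNA molecule and is counted at
#' most once per site. When both mates of a pair carry an aligned base
#' over the site, consistent calls are counted once with the higher of
#' the two qualities; inconsistent calls discard the fragment.
#'
#' @param base1,base2 The two mates' bases at the site.
#' @param qual1,qual2 Their Phred base qualities.
#' @return `list(base=, qual=)` for a counted call, or `NULL` (discard).
#' @examples
#' resolve_fragment_overlap("A", 30, "A", 20)  # counted once, quality 30
#' resolve_fragment_overlap("A", 30, "G", 30)  # NULL: discarded
#' @export
resolve_fragment_overlap <- function(base1, qual1, base2, qual2) {
  if (base1 != base2) return(NULL)
  list(base = base1, qual = max(qual1, qual2))
}

#' Count reference and alternative allele reads at het-SNPs
#'
#' Produces one row per site tallying reads that passed the mapping- and
#' base-quality filters as reference, alternative or other-allele
#' support, plus diagnostics for every filtered read, under a strict
#' accounting identity: `ref_count + alt_count + other_count +
#' low_baseq_dropped + low_mapq_dropped + duplicates_dropped +
#' mate_conflicts_dropped + overlapping_mates_merged == raw_depth`.
#' `raw_depth` is the number of primary alignments with an aligned base
#' over the position; reads spanning the site with a deletion or splice
#' gap carry no base and are ignored. Improper pairs are reported in a
#' diagnostic column but not filtered.
#'
#' @param alignments Path to a coordinate-sorted, indexed BAM file.
#' @param sites A [het_sites] table.
#' @param options A [counting_options] object.
#' @return A `data.frame` of class `"site_counts"`, one row per site in
#'   input order (sites below `min_depth` omitted when `min_depth > 0`).
#' @export
count_alleles <- function(alignments, sites, options = counting_options()) {
  stopifnot(inherits(sites, "het_sites"))
  if (nrow(sites) == 0L) return(.empty_site_counts())
  bam <- if (inherits(alignments, "BamFile")) Rsamtools::path(alignments) else alignments
  idx <- c(paste0(bam, ".bai"), sub("\\.bam$", ".bai", bam))
  if (!any(file.exists(idx)))
    stop("alignment file must be coordinate-sorted and indexed (.bai missing): ", bam)
  bf <- Rsamtools::BamFile(bam)
  hdr_targets <- names(Rsamtools::scanBamHeader(bf)$targets)
  missing_chr <- setdiff(unique(sites$chrom), hdr_targets)
  if (length(missing_chr) > 0L)
    stop("chromosome(s) absent from alignment header: ",
         paste(missing_chr, collapse = ", "))
  hdr_text <- Rsamtools::scanBamHeader(bf)$text
  hd <- hdr_text[names(hdr_text) == "@HD"]
  if (length(hd) > 0L) {
    so <- grep("^SO:", unlist(hd), value = TRUE)
    if (length(so) > 0L && !any(so == "SO:coordinate"))
      stop("alignment file is not coordinate-sorted (", so[1], ")")
  }

  which <- GenomicRanges::GRanges(sites$chrom,
                                  IRanges::IRanges(sites$pos, sites$pos))
  param <- Rsamtools::ScanBamParam(
    which = which,
    what = c("qname", "flag", "pos", "mapq", "cigar", "seq", "qual",
             "mrnm", "mpos"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  res <- Rsamtools::scanBam(bf, param = param)

  any_dup_flag <- any(vapply(res, function(r)
    any(bitwAnd(r$flag, 0x400L) > 0L), logical(1)))
  detection <- options$duplicate_detection
  if (detection == "auto")
    detection <- if (any_dup_flag) "flag" else "signature"

  rows <- .with_seed(options$rng_seed, {
    lapply(seq_len(nrow(sites)), function(i)
      .count_one_site(res[[i]], sites[i, ], options, detection))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("site_counts", "data.frame")
  if (options$min_depth > 0L) {
    out <- out[out$total_count >= options$min_depth, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("site_counts", "data.frame")
  }
  out
}

.empty_site_counts <- function() {
  out <- data.frame(chrom = character(), pos = integer(),
                    site_id = character(), ref = character(),
                    alt = character(),
                    ref_count = integer(), alt_count = integer(),
                    other_count = integer(), total_count = integer(),
                    raw_depth = integer(), low_baseq_dropped = integer(),
                    low_mapq_dropped = integer(),
                    duplicates_dropped = integer(),
                    mate_conflicts_dropped = integer(),
                    overlapping_mates_merged = integer(),
                    improper_pairs = integer(), stringsAsFactors = FALSE)
  class(out) <- c("site_counts", "data.frame")
  out
}

.count_one_site <- function(r, site, opt, detection) {
  target <- site$pos
  keep <- bitwAnd(r$flag, 0x100L) == 0L & bitwAnd(r$flag, 0x800L) == 0L
  qname <- r$qname[keep]; flag <- r$flag[keep]; pos <- r$pos[keep]
  mapq <- r$mapq[keep]; cigar <- r$cigar[keep]
  seqs <- as.character(r$seq)[keep]; quals <- as.character(r$qual)[keep]
  mpos <- r$mpos[keep]

  off <- .query_offset(pos, cigar, target)
  has_base <- !is.na(off)
  raw_depth <- sum(has_base)
  row <- data.frame(chrom = site$chrom, pos = site$pos,
                    site_id = site$site_id, ref = site$ref, alt = site$alt,
                    ref_count = 0L, alt_count = 0L, other_count = 0L,
                    total_count = 0L, raw_depth = raw_depth,
                    low_baseq_dropped = 0L, low_mapq_dropped = 0L,
                    duplicates_dropped = 0L, mate_conflicts_dropped = 0L,
                    overlapping_mates_merged = 0L, improper_pairs = 0L,
                    stringsAsFactors = FALSE)
  if (raw_depth == 0L) return(row)

  qname <- qname[has_base]; flag <- flag[has_base]; pos <- pos[has_base]
  mapq <- mapq[has_base]; cigar <- cigar[has_base]; mpos <- mpos[has_base]
  off <- off[has_base]
  base <- toupper(substring(seqs[has_base], off, off))
  bq <- utf8ToInt(paste(substring(quals[has_base], off, off),
                        collapse = "")) - 33L

  paired <- bitwAnd(flag, 0x1L) > 0L
  row$improper_pairs <- sum(paired &
    (bitwAnd(flag, 0x2L) == 0L | bitwAnd(flag, 0x8L) > 0L))

  mapq[is.na(mapq)] <- 0L
  low_mq <- mapq < opt$min_mapping_quality
  row$low_mapq_dropped <- sum(low_mq)
  live <- which(!low_mq)

  if (opt$remove_duplicates && length(live) > 1L) {
    if (detection == "flag") {
      is_dup <- bitwAnd(flag[live], 0x400L) > 0L
      row$duplicates_dropped <- sum(is_dup)
      live <- live[!is_dup]
    } else {
      ustart <- pos[live] - .leading_clip(cigar[live])
      key <- paste(bitwAnd(flag[live], 0x10L), ustart,
                   ifelse(is.na(mpos[live]), -1L, mpos[live]))
      dropped <- 0L
      keep_idx <- integer(0)
      for (k in split(seq_along(live), key)) {
        if (length(k) == 1L) { keep_idx <- c(keep_idx, k); next }
        sel <- select_duplicate_representative(bq[live[k]],
                                               opt$duplicate_policy)
        keep_idx <- c(keep_idx, k[sel])
        dropped <- dropped + length(k) - 1L
      }
      row$duplicates_dropped <- dropped
      live <- live[sort(keep_idx)]
    }
  }

  if (opt$count_fragments_once && length(live) > 1L) {
    merged <- 0L; conflicts <- 0L
    keep2 <- integer(0)
    for (k in split(live, qname[live])) {
      if (length(k) == 1L) { keep2 <- c(keep2, k); next }
      if (length(unique(base[k])) == 1L) {
        rep_i <- k[which.max(bq[k])]
        keep2 <- c(keep2, rep_i)
        merged <- merged + length(k) - 1L
      } else {
        conflicts <- conflicts + length(k)
      }
    }
    row$overlapping_mates_merged <- merged
    row$mate_conflicts_dropped <- conflicts
    live <- sort(keep2)
  }

  low_bq <- bq[live] < opt$min_base_quality
  row$low_baseq_dropped <- sum(low_bq)
  live <- live[!low_bq]

  b <- base[live]
  row$ref_count <- sum(b == site$ref)
  row$alt_count <- sum(b == site$alt)
  row$other_count <- length(b) - row$ref_count - row$alt_count
  row$total_count <- row$ref_count + row$alt_count
  row
}

# GATK-style column order for the counts table; three diagnostic columns
# appended so the full record round-trips.
.COUNTS_COLS <- c(contig = "chrom", position = "pos", variantID = "site_id",
                  refAllele = "ref", altAllele = "alt",
                  refCount = "ref_count", altCount = "alt_count",
                  totalCount = "total_count",
                  lowMAPQDepth = "low_mapq_dropped",
                  lowBaseQDepth = "low_baseq_dropped",
                  rawDepth = "raw_depth", otherBases = "other_count",
                  improperPairs = "improper_pairs",
                  duplicatesDropped = "duplicates_dropped",
                  mateConflictsDropped = "mate_conflicts_dropped",
                  matesMerged = "overlapping_mates_merged")

#' Write or read a per-site allele counts table
#'
#' Tab-separated, one row per site, with GATK-style columns
#' `contig position variantID refAllele altAllele refCount altCount
#' totalCount lowMAPQDepth lowBaseQDepth rawDepth otherBases
#' improperPairs` followed by `duplicatesDropped mateConflictsDropped
#' matesMerged`. `read_counts_table()` restores the `site_counts`
#' object losslessly.
#'
#' @param counts A `site_counts` table from [count_alleles()].
#' @param path File path.
#' @return `write_counts_table()` returns `path` invisibly;
#'   `read_counts_table()` returns a `site_counts` data frame.
#' @export
write_counts_table <- function(counts, path) {
  df <- as.data.frame(counts)[, .COUNTS_COLS, drop = FALSE]
  names(df) <- names(.COUNTS_COLS)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_table
#' @export
read_counts_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(contig = "character",
                                  variantID = "character"))
  missing <- setdiff(names(.COUNTS_COLS), names(df))
  if (length(missing) > 0L)
    stop("counts table lacks column(s): ", paste(missing, collapse = ", "))
  out <- df[, names(.COUNTS_COLS), drop = FALSE]
  names(out) <- unname(.COUNTS_COLS)
  out <- out[, names(.empty_site_counts()), drop = FALSE]
  class(out) <- c("site_counts", "data.frame")
  out
}

#' @export
print.site_counts <- function(x, ...) {
  cat("Allele counts at", nrow(x), "het-SNP site(s)\n")
  if (nrow(x) > 0L) {
    cat(sprintf("  total counted reads: %d (ref %d / alt %d / other %d)\n",
                sum(x$total_count) + sum(x$other_count),
                sum(x$ref_count), sum(x$alt_count), sum(x$other_count)))
    print.data.frame(head(as.data.frame(x), 10L))
    if (nrow(x) > 10L) cat("  ...", nrow(x) - 10L, "more rows\n")
  }
  invisible(x)
}
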