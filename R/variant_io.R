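# Loading heterozygous SNPs from VCF and applying positional blacklists.
#
# Coordinate conventions: VCF positions are 1-based; BED intervals are
# 0-based half-open. Conversion happens once, at load time. Internally a
# het-site table carries 1-based positions and a filter mask carries
# 0-based half-open intervals.

.VALID_BASES <- c("A", "C", "G", "T")

#' Construct a table of heterozygous SNP sites
#'
#' The unit of allelic-expression measurement is the bi-allelic
#' heterozygous SNP ("het-SNP"): one genomic position at which the
#' individual carries the reference and one alternative base.
#'
#' @param chrom Chromosome names (character).
#' @param pos 1-based positions (integer, >= 1).
#' @param ref,alt Single bases in A/C/G/T; `ref != alt` element-wise.
#' @param site_id Identifier strings; `"."` if unnamed.
#' @return A `data.frame` of class `"het_sites"` with columns
#'   `chrom`, `pos`, `site_id`, `ref`, `alt`, sorted by (chrom, pos).
#' @examples
#' het_sites("chr1", c(100L, 200L), c("A", "C"), c("G", "T"))
#' @export
het_sites <- function(chrom, pos, ref, alt, site_id = ".") {
  pos <- as.integer(pos)
  n <- length(pos)
  site_id <- rep_len(as.character(site_id), n)
  chrom <- rep_len(as.character(chrom), n)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  if (any(pos < 1L)) stop("positions must be >= 1 (1-based)")
  if (!all(ref %in% .VALID_BASES) || !all(alt %in% .VALID_BASES))
    stop("ref and alt alleles must be single bases in A/C/G/T (SNPs only)")
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  out <- data.frame(chrom = chrom, pos = pos, site_id = site_id,
                    ref = ref, alt = alt, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  if (anyDuplicated(paste(out$chrom, out$pos)))
    stop("duplicate site positions are not allowed")
  rownames(out) <- NULL
  class(out) <- c("het_sites", "data.frame")
  out
}

#' Load bi-allelic heterozygous SNPs from a VCF file
#'
#' Keeps only records that are SNPs (single-base REF and ALT) and
#' bi-allelic; multi-allelic and indel records are skipped with a counted
#' warning. When `sample` is given, only sites genotyped heterozygous
#' (0/1, 0|1 or 1|0) for that sample are kept; phased and unphased
#' heterozygotes are treated identically. Without `sample`, every
#' bi-allelic SNP record is returned as a candidate het site.
#'
#' @param vcf_path Path to a VCF v4.x file (plain or bgzip).
#' @param sample Sample name whose genotypes define heterozygosity, or
#'   `NULL` to skip genotype filtering.
#' @return A [het_sites] table sorted by (chrom, pos).
#' @export
load_het_sites <- function(vcf_path, sample = NULL) {
  if (!file.exists(vcf_path)) stop("VCF file not found: ", vcf_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(het_sites(character(), integer(), character(), character()))
  ref <- toupper(fix$REF)
  alt <- toupper(fix$ALT)
  is_snp <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1L & !grepl(",", alt, fixed = TRUE) & nchar(alt) == 1L &
    ref %in% .VALID_BASES & alt %in% .VALID_BASES
  n_skip <- sum(!is_snp)
  if (n_skip > 0L)
    warning(n_skip, " multi-allelic or non-SNP record(s) skipped")
  keep <- is_snp
  if (!is.null(sample)) {
    if (ncol(v@gt) < 2L)
      stop("VCF has no genotype columns but a sample was requested")
    if (!sample %in% colnames(v@gt))
      stop("sample '", sample, "' not found in VCF")
    gt <- vcfR::extract.gt(v, element = "GT")[, sample]
    het <- !is.na(gt) & gt %in% c("0/1", "0|1", "1|0", "1/0")
    keep <- keep & het
  }
  fix <- fix[keep, , drop = FALSE]
  if (nrow(fix) == 0L) return(het_sites(character(), integer(), character(), character()))
  het_sites(chrom = fix$CHROM, pos = as.integer(fix$POS),
            ref = fix$REF, alt = fix$ALT,
            site_id = ifelse(is.na(fix$ID), ".", fix$ID))
}

#' Construct a positional site-filter mask
#'
#' A mask is a set of genomic intervals (0-based half-open, the BED
#' convention) within which het-SNPs are discarded — typically regions of
#' low mappability or sites showing allelic mapping bias in simulation.
#' Overlapping or book-ended intervals are merged on construction.
#'
#' @param x A BED file path, or a `data.frame` with columns `chrom`,
#'   `start`, `end` already in 0-based half-open coordinates.
#' @param label A name for the filter (e.g. `"low_mappability"`).
#' @return An object of class `"site_filter_mask"`: a `data.frame` of
#'   merged intervals with a `label` attribute.
#' @export
site_filter_mask <- function(x, label = "site_filter") {
  if (is.character(x) && length(x) == 1L) {
    gr <- rtracklayer::import(x, format = "BED")
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(x, stringsAsFactors = FALSE)
    stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  }
  if (nrow(df) > 0L) {
    if (any(df$start >= df$end)) stop("mask intervals need start < end")
    # merge overlaps per chromosome (half-open: touching intervals merge)
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      df$chrom, IRanges::IRanges(start = df$start + 1L, end = df$end)))
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     stringsAsFactors = FALSE)
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(df, label = label, class = c("site_filter_mask", "data.frame"))
}

#' Remove het-SNPs falling inside masked regions
#'
#' A site is removed when its 1-based position lies inside any mask
#' interval; with the half-open convention, a site at the interval `end`
#' coordinate is retained. Input order is preserved. An empty mask is the
#' identity. Chromosome naming styles must agree between sites and mask
#' ("chr1" vs "1" is an error, not silently harmonized).
#'
#' @param sites A [het_sites] table.
#' @param mask A [site_filter_mask].
#' @return The retained sites, with attribute `n_removed`.
#' @export
apply_site_filter <- function(sites, mask) {
  if (nrow(mask) == 0L || nrow(sites) == 0L) {
    attr(sites, "n_removed") <- 0L
    return(sites)
  }
  .check_chrom_style(unique(sites$chrom), unique(mask$chrom))
  hit <- rep(FALSE, nrow(sites))
  for (ch in unique(mask$chrom)) {
    m <- mask[mask$chrom == ch, , drop = FALSE]
    idx <- which(sites$chrom == ch)
    if (length(idx) == 0L) next
    # a site at the half-open interval's end coordinate is retained
    inside <- vapply(sites$pos[idx], function(p)
      any(m$start <= p & p < m$end), logical(1))
    hit[idx] <- inside
  }
  out <- sites[!hit, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(sites)
  attr(out, "n_removed") <- sum(hit)
  out
}

# "chr1" vs "1" style mismatches hide input errors; refuse them.
.check_chrom_style <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(invisible(TRUE))
  strip <- function(x) sub("^chr", "", x)
  if (length(intersect(a, b)) == 0L &&
      length(intersect(strip(a), strip(b))) > 0L)
    stop("chromosome naming styles disagree (e.g. 'chr1' vs '1'); ",
         "harmonize inputs explicitly")
  invisible(TRUE)
}

#' Write a het-site table to VCF or TSV
#'
#' The VCF output is a minimal sites-only VCF v4.2 that round-trips
#' through [load_het_sites()].
#'
#' @param sites A [het_sites] table.
#' @param path Output file path.
#' @param format `"vcf"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_het_sites <- function(sites, path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(as.data.frame(sites), path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  hdr <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- if (nrow(sites) > 0L) {
    paste(sites$chrom, sites$pos, sites$site_id, sites$ref, sites$alt,
          ".", ".", ".", sep = "\t")
  } else character()
  writeLines(c(hdr, rows), path)
  invisible(path)
}
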