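# Fixtures built in code. The hand SAM fixture is a 20-read pileup at
# one site (chr1:100, REF=A, ALT=G, reads 10 bp) whose expected tallies
# were enumerated by hand; see the comment on each read.

HAND_SAM_EXPECTED <- list(
  ref = 4L, alt = 3L, other = 2L, total = 7L, raw_depth = 16L,
  low_baseq = 1L, low_mapq = 1L, dups = 2L, conflicts = 2L, merged = 1L,
  improper = 1L)

hand_sam_fixture <- function(dir = tempfile("handsam")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Q <- "IIIIIIIIII"                       # phred 40 everywhere
  rows <- list(
    # qname flag pos mapq cigar rnext pnext tlen seq qual
    c("r01", 0, 95, 60, "10M", "*", 0, 0, "AAAAAAAAAA", Q),  # ref
    c("r02", 0, 95, 60, "10M", "*", 0, 0, "AAAAAAAAAA", Q),  # ref
    c("r03", 0, 95, 60, "10M", "*", 0, 0, "AAAAAAAAAA",
      "IIIII#IIII"),                      # base qual 2 at site -> low_bq
    c("r04", 0, 95, 60, "10M", "*", 0, 0, "AAAAAGAAAA", Q),  # alt
    c("r05", 0, 95, 60, "10M", "*", 0, 0, "AAAAAGAAAA", Q),  # alt
    c("r06", 0, 95, 60, "10M", "*", 0, 0, "AAAAATAAAA", Q),  # other (T)
    c("r07", 0, 95,  5, "10M", "*", 0, 0, "AAAAAAAAAA", Q),  # low mapq
    c("r08", 1024, 95, 60, "10M", "*", 0, 0, "AAAAAAAAAA", Q), # dup flag
    c("r09", 1024, 95, 60, "10M", "*", 0, 0, "AAAAAGAAAA", Q), # dup flag
    # proper pair, both mates over the site, consistent A -> count once
    c("p01",  99, 93, 60, "10M", "=", 97,  14, "AAAAAAAAAA", Q),
    c("p01", 147, 97, 60, "10M", "=", 93, -14, "AAAAAAAAAA", Q),
    # proper pair, discordant base calls at the site -> both dropped
    c("p02",  99, 93, 60, "10M", "=", 97,  14, "AAAAAAAAAA", Q),
    c("p02", 147, 97, 60, "10M", "=", 93, -14, "AAAGAAAAAA", Q),
    # deletion spans the site: no aligned base, ignored
    c("r10", 0, 95, 60, "4M2D6M", "*", 0, 0, "AAAAAAAAAA", Q),
    # secondary alignment: excluded before raw_depth
    c("r11", 256, 95, 60, "10M", "*", 0, 0, "AAAAAAAAAA", Q),
    # splice gap over the site: ignored
    c("r12", 0, 90, 60, "5M20N5M", "*", 0, 0, "AAAAAAAAAA", Q),
    # paired with unmapped mate: counted (ref) but flagged improper
    c("r13", 9, 95, 60, "10M", "*", 0, 0, "AAAAAAAAAA", Q),
    # leading soft clip; aligned base at site is G -> alt
    c("r14", 0, 98, 60, "2S8M", "*", 0, 0, "TTAAGAAAAA", Q),
    # N base at the site -> other
    c("r15", 0, 95, 60, "10M", "*", 0, 0, "AAAAANAAAA", Q),
    # unmapped: never fetched
    c("r16", 4, 0, 0, "*", "*", 0, 0, "AAAAAAAAAA", Q))
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(t(r))))
  names(df) <- c("qname", "flag", "pos", "mapq", "cigar", "rnext",
                 "pnext", "tlen", "seq", "qual")
  df$pos <- as.integer(df$pos)
  mapped <- df[df$flag != "4", ]
  mapped <- mapped[order(mapped$pos), ]
  unmapped <- df[df$flag == "4", ]
  sam <- file.path(dir, "hand.sam")
  fmt <- function(d) apply(d, 1, function(r) {
    paste(r["qname"], r["flag"], ifelse(r["flag"] == "4", "*", "chr1"),
          r["pos"], r["mapq"], r["cigar"], r["rnext"], r["pnext"],
          r["tlen"], r["seq"], r["qual"], sep = "\t")
  })
  writeLines(c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chr1\tLN:1000",
               fmt(mapped), fmt(unmapped)), sam)
  bam <- suppressMessages(Rsamtools::asBam(
    sam, destination = file.path(dir, "hand"), overwrite = TRUE,
    indexDestination = TRUE))
  list(sam = sam, bam = bam,
       site = het_sites("chr1", 100L, "A", "G", site_id = "rs1"))
}

# Small VCF fixture: a het SNP, a hom-ref SNP, an indel, a multi-allelic
# record and a phased het.
write_vcf_fixture <- function(path, with_genotypes = TRUE) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (with_genotypes) {
    hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tNA1")
    rows <- c("chr1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/1",
              "chr1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0/0",
              "chr1\t300\trs3\tAT\tA\t.\tPASS\t.\tGT\t0/1",
              "chr1\t400\trs4\tG\tA,C\t.\tPASS\t.\tGT\t1/2",
              "chr1\t500\trs5\tT\tC\t.\tPASS\t.\tGT\t1|0")
  } else {
    hdr <- c(hdr[1], "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    rows <- c("chr1\t100\trs1\tA\tG\t.\tPASS\t.",
              "chr1\t200\trs2\tC\tT\t.\tPASS\t.",
              "chr1\t300\trs3\tAT\tA\t.\tPASS\t.",
              "chr1\t400\trs4\tG\tA,C\t.\tPASS\t.",
              "chr1\t500\trs5\tT\tC\t.\tPASS\t.")
  }
  writeLines(c(hdr, rows), path)
  path
}

# Minimal site_counts constructor for statistics-level tests.
make_counts <- function(ref, alt, other = 0L, chrom = "chr1",
                        pos = seq_along(ref) * 100L) {
  n <- length(ref)
  other <- rep_len(other, n)
  out <- data.frame(chrom = rep_len(chrom, n), pos = pos,
                    site_id = sprintf("s%03d", seq_len(n)),
                    ref = rep_len("A", n), alt = rep_len("G", n),
                    ref_count = as.integer(ref), alt_count = as.integer(alt),
                    other_count = as.integer(other),
                    total_count = as.integer(ref + alt),
                    raw_depth = as.integer(ref + alt + other),
                    low_baseq_dropped = rep_len(0L, n),
                    low_mapq_dropped = rep_len(0L, n),
                    duplicates_dropped = rep_len(0L, n),
                    mate_conflicts_dropped = rep_len(0L, n),
                    overlapping_mates_merged = rep_len(0L, n),
                    improper_pairs = rep_len(0L, n),
                    stringsAsFactors = FALSE)
  class(out) <- c("site_counts", "data.frame")
  out
}

# The read-accounting conservation identity.
conservation_holds <- function(counts) {
  lhs <- counts$ref_count + counts$alt_count + counts$other_count +
    counts$low_baseq_dropped + counts$low_mapq_dropped +
    counts$duplicates_dropped + counts$mate_conflicts_dropped +
    counts$overlapping_mates_merged
  all(lhs == counts$raw_depth)
}
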