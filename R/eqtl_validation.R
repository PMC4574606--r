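# Gene-level AE and the eQTL validation analysis: individuals
# heterozygous for a gene's top eQTL SNP (eSNP) are expected to show
# elevated allelic expression at that gene relative to eSNP homozygotes,
# giving an external yardstick for AE data quality.

#' Summarize AE per gene and individual
#'
#' For one individual, the median AE effect size over the qualifying
#' sites (ref+alt reads at or above `min_depth`) contained in each gene.
#' Genes with no qualifying site are omitted. A site inside several
#' overlapping genes contributes to each of them.
#'
#' @param results An `ae_results` table (one individual), or any
#'   `data.frame` with `chrom`, `pos`, `total_count`, `effect_size`.
#' @param genes Gene intervals: a `data.frame` with `gene_id`, `chrom`,
#'   `start`, `end` (1-based, inclusive) or a `GRanges` with a
#'   `gene_id` metadata column.
#' @param individual_id Identifier recorded in the output.
#' @param min_depth Minimum ref+alt reads for a site to contribute.
#' @return A `data.frame` with `gene_id`, `individual_id`, `median_ae`,
#'   `n_sites`.
#' @export
gene_level_ae <- function(results, genes, individual_id = "sample",
                          min_depth = 16L) {
  if (inherits(genes, "GRanges")) {
    if (is.null(genes$gene_id)) stop("genes GRanges needs a gene_id column")
    genes <- data.frame(gene_id = genes$gene_id,
                        chrom = as.character(GenomicRanges::seqnames(genes)),
                        start = GenomicRanges::start(genes),
                        end = GenomicRanges::end(genes),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  if (any(genes$start > genes$end)) stop("malformed gene intervals")
  df <- as.data.frame(results)
  df <- df[df$total_count >= min_depth, , drop = FALSE]
  if (nrow(df) == 0L)
    return(data.frame(gene_id = character(), individual_id = character(),
                      median_ae = numeric(), n_sites = integer(),
                      stringsAsFactors = FALSE))
  sgr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos, df$pos))
  ggr <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$start, genes$end))
  ov <- GenomicRanges::findOverlaps(sgr, ggr)
  if (length(ov) == 0L)
    return(data.frame(gene_id = character(), individual_id = character(),
                      median_ae = numeric(), n_sites = integer(),
                      stringsAsFactors = FALSE))
  eff <- split(df$effect_size[S4Vectors::queryHits(ov)],
               genes$gene_id[S4Vectors::subjectHits(ov)])
  out <- data.frame(gene_id = names(eff),
                    individual_id = individual_id,
                    median_ae = vapply(eff, median, numeric(1)),
                    n_sites = lengths(eff),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Compare gene-level AE between eSNP heterozygotes and homozygotes
#'
#' For each gene with at least `min_per_class` AE measurements in both
#' genotype classes, a Wilcoxon rank-sum test of the difference in
#' median AE, BH-corrected across genes. The expected direction of a
#' genuine cis-regulatory signal is higher AE in eSNP heterozygotes;
#' significant genes in the opposite direction indicate artifacts.
#' Both homozygote genotypes are pooled into one class.
#'
#' @param measures Output of [gene_level_ae()] rows (all individuals),
#'   with an `esnp_genotype` column in
#'   `{"heterozygous", "homozygous"}`.
#' @param min_per_class Minimum AE measurements per genotype class.
#' @param fdr FDR level across genes.
#' @return A `data.frame` per tested gene: `gene_id`, `n_het`, `n_hom`,
#'   `median_het`, `median_hom`, `p_value`, `q_value`, `significant`,
#'   `direction` (`"het_gt_hom"` or `"hom_gt_het"`).
#' @export
compare_het_vs_hom <- function(measures, min_per_class = 30L, fdr = 0.01) {
  stopifnot("esnp_genotype" %in% names(measures))
  bad <- setdiff(unique(measures$esnp_genotype),
                 c("heterozygous", "homozygous"))
  if (length(bad) > 0L)
    stop("unknown esnp_genotype value(s): ", paste(bad, collapse = ", "))
  res <- lapply(split(measures, measures$gene_id), function(g) {
    het <- g$median_ae[g$esnp_genotype == "heterozygous"]
    hom <- g$median_ae[g$esnp_genotype == "homozygous"]
    if (length(het) < min_per_class || length(hom) < min_per_class)
      return(NULL)
    # exact for small untied samples; normal approximation with tie
    # correction otherwise (wilcox.test's own switch)
    p <- suppressWarnings(wilcox.test(het, hom)$p.value)
    data.frame(gene_id = g$gene_id[1], n_het = length(het),
               n_hom = length(hom), median_het = median(het),
               median_hom = median(hom), p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(gene_id = character(), n_het = integer(),
                      n_hom = integer(), median_het = numeric(),
                      median_hom = numeric(), p_value = numeric(),
                      q_value = numeric(), significant = logical(),
                      direction = character(), stringsAsFactors = FALSE))
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value <= fdr
  out$direction <- ifelse(out$median_het >= out$median_hom,
                          "het_gt_hom", "hom_gt_het")
  rownames(out) <- NULL
  out
}

#' Proportion of individuals with allelic imbalance, by genotype class
#'
#' Per gene and eSNP genotype class, the fraction of individuals whose
#' gene-level median AE exceeds `threshold`. Effect sizes cannot exceed
#' 0.5, so a threshold of 0.5 always yields 0.
#'
#' @param measures As in [compare_het_vs_hom()].
#' @param threshold AE effect-size threshold.
#' @return A `data.frame` with `gene_id`, `esnp_genotype`,
#'   `n_individuals`, `proportion_imbalanced`.
#' @export
imbalance_proportion_by_class <- function(measures, threshold = 0.25) {
  stopifnot("esnp_genotype" %in% names(measures))
  agg <- split(measures, list(measures$gene_id, measures$esnp_genotype),
               drop = TRUE)
  out <- do.call(rbind, lapply(agg, function(g)
    data.frame(gene_id = g$gene_id[1], esnp_genotype = g$esnp_genotype[1],
               n_individuals = nrow(g),
               proportion_imbalanced = mean(g$median_ae > threshold),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$gene_id, out$esnp_genotype), , drop = FALSE]
}
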