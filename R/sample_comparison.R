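# Between-sample sharing of allelic expression and MDS embedding.
#
# The distance between two samples is the fraction of their shared AE
# sites at which exactly one of the two shows significant imbalance:
#   d(A, B) = |sites significant in only one| / |shared sites|.
# Shared sites are those tested (depth + QC passed) in BOTH samples.

#' Pairwise AE distance between two samples
#'
#' @param sigA,sigB Identifiers of the significant-AE sites of each
#'   sample.
#' @param sharedAB Identifiers of the sites with AE data in both
#'   samples.
#' @return The distance in `[0, 1]`, or `NA` (with a warning) when no
#'   site is shared.
#' @examples
#' pairwise_ae_distance(c("s1", "s2"), c("s2", "s3"),
#'                      c("s1", "s2", "s3", "s4"))  # 0.5
#' @export
pairwise_ae_distance <- function(sigA, sigB, sharedAB) {
  shared <- unique(sharedAB)
  if (length(shared) == 0L) {
    warning("no shared sites; distance undefined")
    return(NA_real_)
  }
  a <- intersect(unique(sigA), shared)
  b <- intersect(unique(sigB), shared)
  discordant <- length(setdiff(a, b)) + length(setdiff(b, a))
  discordant / length(shared)
}

#' AE distance matrix over a cohort
#'
#' Runs the pairwise AE distance over every sample pair. Each element of
#' `results_list` is an `ae_results` table (from [ae_test()]); its rows
#' define the sample's tested-site universe and its `significant` column
#' the significant set, optionally re-called here at a different FDR /
#' effect-size cutoff.
#'
#' @param results_list Named list of `ae_results` tables.
#' @param fdr,min_effect When not `NULL`, significance is re-called per
#'   sample with [call_significant_sites()] at these settings.
#' @return An object of class `"ae_dist"`: list with `sample_ids`, the
#'   distance matrix `d` (NA where no sites are shared) and
#'   `shared_counts`.
#' @export
ae_distance_matrix <- function(results_list, fdr = NULL, min_effect = NULL) {
  stopifnot(is.list(results_list), length(results_list) >= 2L)
  ids <- names(results_list)
  if (is.null(ids) || any(ids == ""))
    stop("results_list must be a named list of samples")
  key <- function(r) paste(r$chrom, r$pos, sep = ":")
  universes <- lapply(results_list, key)
  sigs <- lapply(results_list, function(r) {
    if (!is.null(fdr))
      r <- call_significant_sites(r, fdr = fdr, min_effect = min_effect)
    key(r)[r$significant]
  })
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  sh <- matrix(0L, n, n, dimnames = list(ids, ids))
  diag(sh) <- lengths(universes)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    shared <- intersect(universes[[i]], universes[[j]])
    sh[i, j] <- sh[j, i] <- length(shared)
    dij <- suppressWarnings(
      pairwise_ae_distance(sigs[[i]], sigs[[j]], shared))
    d[i, j] <- d[j, i] <- dij
  }
  if (anyNA(d)) warning("some sample pairs share no sites (distance NA)")
  structure(list(sample_ids = ids, d = d, shared_counts = sh),
            class = "ae_dist")
}

#' Classical multidimensional scaling of an AE distance matrix
#'
#' Torgerson scaling via [stats::cmdscale()]: double-centre the squared
#' distances, eigendecompose, and return the top-`k` coordinates scaled
#' by root eigenvalues. Axes are defined up to sign and rotation.
#' Negative eigenvalues (the AE distance is not guaranteed Euclidean)
#' are truncated to zero with a warning.
#'
#' @param dist An `ae_dist` object or a symmetric distance matrix.
#' @param k Number of dimensions.
#' @return List with `points` (n x k coordinate matrix) and `eig`.
#' @export
classical_mds <- function(dist, k = 2L) {
  d <- if (inherits(dist, "ae_dist")) dist$d else as.matrix(dist)
  stopifnot(k >= 1)
  if (anyNA(d))
    stop("distance matrix has undefined cells; impute or drop samples first")
  fit <- cmdscale(d, k = min(k, nrow(d) - 1L), eig = TRUE)
  if (any(fit$eig < -sqrt(.Machine$double.eps) * max(abs(fit$eig), 1)))
    warning("negative eigenvalues truncated: distances are not Euclidean")
  pts <- fit$points
  if (ncol(pts) < k) {  # degenerate (e.g. all-zero) matrices
    pts <- cbind(pts, matrix(0, nrow(d), k - ncol(pts)))
    rownames(pts) <- rownames(d)
  }
  list(points = pts, eig = fit$eig)
}
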