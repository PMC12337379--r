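#' PCA of the DMR score matrix
#'
#' Samples are projected onto the principal components of the (centred,
#' optionally unit-scaled) DMR-by-sample score matrix. Missing per-sample
#' scores are imputed by the per-DMR cohort mean and counted. The sign of
#' each component is fixed so that its largest-magnitude loading is
#' positive, making coordinates reproducible across platforms.
#'
#' @param scores Numeric matrix DMRs x samples (from [score_segments()]).
#' @param center Centre DMR scores (default `TRUE`).
#' @param scale. Scale DMR scores to unit variance (default `FALSE`;
#'   fraction-scale scores are already commensurate). Constant DMRs are
#'   dropped with a warning when scaling.
#' @return List with `coords` (samples x PCs), `var_explained`,
#'   `loadings`, `n_imputed`.
#' @export
dmr_pca <- function(scores, center = TRUE, scale. = FALSE) {
  stopifnot(ncol(scores) >= 3L, nrow(scores) >= 2L)
  n_imputed <- sum(is.na(scores))
  if (n_imputed > 0L) {
    rm <- rowMeans(scores, na.rm = TRUE)
    idx <- which(is.na(scores), arr.ind = TRUE)
    scores[idx] <- rm[idx[, 1L]]
  }
  if (scale.) {
    const <- apply(scores, 1L, sd) == 0
    if (any(const)) {
      warning(sum(const), " constant DMR row(s) dropped for scaling")
      scores <- scores[!const, , drop = FALSE]
    }
  }
  pc <- prcomp(t(scores), center = center, scale. = scale.)
  flip <- apply(pc$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  coords <- sweep(pc$x, 2L, flip, "*")
  loadings <- sweep(pc$rotation, 2L, flip, "*")
  list(coords = coords,
       var_explained = pc$sdev^2 / sum(pc$sdev^2),
       loadings = loadings, n_imputed = n_imputed)
}

#' Hierarchical clustering of samples on DMR scores
#'
#' Agglomerative clustering of the samples with a k = 2 cut, the
#' discrimination view of the DMR score matrix. Merge order under equal
#' heights follows the deterministic lowest-index convention of
#' [stats::hclust()].
#'
#' @param scores Numeric matrix DMRs x samples; `NA` imputed as in
#'   [dmr_pca()].
#' @param distance `"euclidean"` or `"correlation"` (1 - Pearson r).
#' @param linkage `"ward"` (Ward.D2), `"complete"` or `"average"`.
#' @param k Number of clusters for the cut (default 2).
#' @param groups Optional true labels; when given, a confusion table of
#'   cut membership against them is returned.
#' @return List with `hclust`, `clusters` (named membership vector),
#'   `newick` (tree string) and optionally `confusion`.
#' @export
dmr_hclust <- function(scores, distance = c("euclidean", "correlation"),
                       linkage = c("ward", "complete", "average"),
                       k = 2L, groups = NULL) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (anyNA(scores)) {
    rm <- rowMeans(scores, na.rm = TRUE)
    idx <- which(is.na(scores), arr.ind = TRUE)
    scores[idx] <- rm[idx[, 1L]]
  }
  x <- t(scores)
  d <- if (distance == "euclidean") dist(x)
       else stats::as.dist(1 - stats::cor(t(x)))
  method <- c(ward = "ward.D2", complete = "complete",
              average = "average")[[linkage]]
  hc <- hclust(d, method = method)
  cl <- cutree(hc, k = k)
  out <- list(hclust = hc, clusters = cl,
              newick = ape::write.tree(ape::as.phylo(hc)))
  if (!is.null(groups)) out$confusion <- table(cluster = cl, group = groups)
  out
}

#' CpG-level correlation between two methylomes
#'
#' Pearson correlation of methylation fractions over the CpG sites
#' covered at `min_cov` in both samples, or — when `restrict_to` supplies
#' a DMR set — over per-DMR coverage-weighted scores. Averaging over DMRs
#' suppresses per-site sampling noise, so the DMR-restricted correlation
#' of a high/low-coverage replicate pair exceeds its all-site
#' correlation.
#'
#' @param a,b [sample_methylome()] objects.
#' @param min_cov Minimum `n_valid` in both samples per site (default 3).
#' @param restrict_to Optional segment table (`chrom`, `start`, `end`).
#' @return List with `r`, `n_sites` and `flagged` (`TRUE` with `r = NA`
#'   when fewer than 10 shared sites/segments are available).
#' @export
sample_correlation <- function(a, b, min_cov = 3L, restrict_to = NULL) {
  ra <- a$records[n_valid >= min_cov]
  rb <- b$records[n_valid >= min_cov]
  m <- merge(ra[, .(chrom, start, fa = frac, ma = n_mod, ta = n_valid)],
             rb[, .(chrom, start, fb = frac, mb = n_mod, tb = n_valid)],
             by = c("chrom", "start"))
  if (is.null(restrict_to)) {
    if (nrow(m) < 10L)
      return(list(r = NA_real_, n_sites = nrow(m), flagged = TRUE))
    return(list(r = cor(m$fa, m$fb), n_sites = nrow(m), flagged = FALSE))
  }
  seg <- as.data.table(restrict_to)
  sa <- sb <- numeric(nrow(seg))
  ok <- logical(nrow(seg))
  for (i in seq_len(nrow(seg))) {
    s <- m[chrom == seg$chrom[i] & start >= seg$start[i] &
             start < seg$end[i]]
    if (nrow(s) == 0L) next
    sa[i] <- sum(s$ma) / sum(s$ta)
    sb[i] <- sum(s$mb) / sum(s$tb)
    ok[i] <- TRUE
  }
  if (sum(ok) < 10L)
    return(list(r = NA_real_, n_sites = sum(ok), flagged = TRUE))
  list(r = cor(sa[ok], sb[ok]), n_sites = sum(ok), flagged = FALSE)
}
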