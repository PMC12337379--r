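#' Assemble a cohort methylation matrix
#'
#' Builds the sites-by-samples count matrices used by all downstream
#' stages. The site universe is the union of CpG sites observed in any
#' sample; per-sample entries are masked when the valid-call coverage falls
#' below `min_cov`.
#'
#' @param methylomes List of [sample_methylome()] objects (>= 2, unique
#'   sample ids).
#' @param min_cov Minimum `n_valid` for a site to count as observed in a
#'   sample (default 3).
#' @return A `cohort_matrix`: list with `sites` (`data.table` of `chrom`,
#'   `start`), `samples` (`data.table` of `sample_id`, `group`, `tier`,
#'   `tumour_fraction`), integer matrices `mod` and `valid`, logical `mask`
#'   (`valid >= min_cov`), and `min_cov`.
#' @export
build_cohort_matrix <- function(methylomes, min_cov = 3L) {
  if (length(methylomes) < 2L) stop("need >= 2 samples")
  ids <- vapply(methylomes, function(m) m$sample_id, character(1L))
  if (anyDuplicated(ids) > 0L)
    stop("duplicate sample ids: ", ids[duplicated(ids)][1L])
  sites <- unique(rbindlist(
    lapply(methylomes, function(m) m$records[, .(chrom, start)])))
  setorder(sites, chrom, start)
  key <- paste(sites$chrom, sites$start)
  n <- nrow(sites)
  p <- length(methylomes)
  mod <- matrix(0L, n, p, dimnames = list(NULL, ids))
  valid <- matrix(0L, n, p, dimnames = list(NULL, ids))
  for (j in seq_len(p)) {
    r <- methylomes[[j]]$records
    idx <- match(paste(r$chrom, r$start), key)
    mod[idx, j] <- r$n_mod
    valid[idx, j] <- r$n_valid
  }
  samples <- data.table(
    sample_id = ids,
    group = vapply(methylomes, function(m) as.character(m$group),
                   character(1L)),
    tier = vapply(methylomes, function(m) as.character(m$coverage_tier),
                  character(1L)),
    tumour_fraction = vapply(methylomes, function(m)
      as.numeric(m$tumour_fraction), numeric(1L)))
  structure(
    list(sites = sites, samples = samples, mod = mod, valid = valid,
         mask = valid >= min_cov, min_cov = as.integer(min_cov)),
    class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat(sprintf("cohort_matrix: %d CpG sites x %d samples (%s), min_cov = %d\n",
              nrow(x$sites), nrow(x$samples),
              paste(sprintf("%d %s", table(x$samples$group),
                            names(table(x$samples$group))), collapse = ", "),
              x$min_cov))
  invisible(x)
}
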