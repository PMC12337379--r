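#' Downsample a methylome to lower coverage
#'
#' Emulates re-sequencing the same sample at a fraction of the depth:
#' each site's valid-call coverage is binomially thinned and the modified
#' calls are drawn hypergeometrically from the original read pool, so the
#' thinned methylome is a faithful low-coverage replicate with the same
#' underlying methylation state.
#'
#' @param m A [sample_methylome()].
#' @param factor Retention fraction in (0, 1], e.g. 0.15 to mimic a 3x
#'   replicate of a 20x run.
#' @param seed Optional integer seed.
#' @param suffix Appended to the sample id (default `"_lowcov"`).
#' @return A [sample_methylome()] with sites of zero thinned coverage
#'   dropped and `coverage_tier = "low"`.
#' @export
thin_methylome <- function(m, factor, seed = NULL, suffix = "_lowcov") {
  stopifnot(inherits(m, "sample_methylome"), factor > 0, factor <= 1)
  if (!is.null(seed)) set.seed(seed)
  r <- m$records
  n_valid <- rbinom(nrow(r), r$n_valid, factor)
  n_mod <- stats::rhyper(nrow(r), r$n_mod, r$n_valid - r$n_mod, n_valid)
  keep <- n_valid > 0L
  rec <- data.table(chrom = r$chrom[keep], start = r$start[keep],
                    end = r$end[keep], strand = r$strand[keep],
                    n_mod = n_mod[keep], n_valid = n_valid[keep])
  sample_methylome(rec, paste0(m$sample_id, suffix), m$group, "low",
                   m$tumour_fraction)
}
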