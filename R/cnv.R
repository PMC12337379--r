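#' Tile a genome into fixed-width bins
#'
#' @param chrom_sizes Named vector of chromosome lengths in bp.
#' @param bin_size Bin width in bp (default 500 kb, the low-pass regime
#'   suited to 2-5x coverage).
#' @return `data.table` of half-open bins (`chrom`, `start`, `end`); the
#'   trailing partial bin of each chromosome is kept.
#' @export
make_bins <- function(chrom_sizes, bin_size = 500e3) {
  if (bin_size <= 0) stop("bin_size must be positive")
  rbindlist(lapply(names(chrom_sizes), function(ch) {
    s <- seq(0, chrom_sizes[[ch]] - 1, by = bin_size)
    data.table(chrom = ch, start = as.integer(s),
               end = as.integer(pmin(s + bin_size, chrom_sizes[[ch]])))
  }))
}

#' Count read positions per bin
#'
#' @param positions `data.table` with `chrom` and `pos` (0-based read
#'   placements).
#' @param bins Bin table from [make_bins()].
#' @return Integer vector of counts, one per bin.
#' @export
bin_counts <- function(positions, bins) {
  counts <- integer(nrow(bins))
  for (ch in unique(bins$chrom)) {
    bi <- which(bins$chrom == ch)
    p <- positions[chrom == ch, pos]
    if (length(p) == 0L) next
    idx <- findInterval(p, bins$start[bi])
    ok <- idx >= 1L & p < bins$end[bi][pmax(idx, 1L)]
    tb <- tabulate(idx[ok], nbins = length(bi))
    counts[bi] <- counts[bi] + tb
  }
  counts
}

#' Normalise binned counts to copy-ratio scale
#'
#' Each sample's counts are scaled to median 1 over analysed bins, then
#' divided by a per-bin reference (the median of the scaled control
#' profiles when `ref` is not supplied) and log2-transformed; the median
#' log2 ratio per sample is re-centred to 0. Bins with a zero reference
#' are masked.
#'
#' @param counts Integer matrix bins x samples.
#' @param bins Bin table.
#' @param groups Character vector of per-sample group labels (used to
#'   pick the control samples when `ref` is `NULL`).
#' @param ref Optional per-bin reference vector.
#' @param ref_group Label of the control group (default `"nonBC"`).
#' @return List of class `cnv_profile`: `bins`, `counts`, `norm` (scaled
#'   counts), `log2_ratio` (matrix), `mask` (analysed bins) and `ref`.
#' @export
cnv_normalize <- function(counts, bins, groups = NULL, ref = NULL,
                          ref_group = "nonBC") {
  counts <- as.matrix(counts)
  sm <- counts + 0.5  # stabilise empty bins at shallow depth
  norm <- sweep(sm, 2L, apply(sm, 2L, median), "/")
  if (is.null(ref)) {
    if (is.null(groups)) stop("need groups or an explicit ref")
    ctrl <- which(groups == ref_group)
    if (length(ctrl) == 0L) stop("no control samples for reference")
    ref <- apply(norm[, ctrl, drop = FALSE], 1L, median)
  }
  mask <- ref > 0
  lr <- log2(sweep(norm, 1L, ifelse(mask, ref, NA_real_), "/"))
  lr <- sweep(lr, 2L, apply(lr, 2L, function(x) median(x[mask])), "-")
  structure(list(bins = as.data.table(bins), counts = counts, norm = norm,
                 log2_ratio = lr, mask = mask, ref = ref),
            class = "cnv_profile")
}

#' Call copy-number gains and losses
#'
#' Rolling-median smoothing of the log2 ratio within each chromosome,
#' per-bin thresholding, and suppression of isolated single-bin calls
#' (reverted to neutral).
#'
#' @param profile A `cnv_profile` from [cnv_normalize()].
#' @param window Rolling-median window in bins (odd, default 5).
#' @param thresholds Length-2 numeric `c(loss, gain)` log2 thresholds
#'   (default `c(-0.2, 0.2)`).
#' @return The profile with a `calls` character matrix
#'   (`gain`/`neutral`/`loss`; `NA` on masked bins) and the smoothed
#'   `log2_smooth` matrix added.
#' @export
cnv_call <- function(profile, window = 5L, thresholds = c(-0.2, 0.2)) {
  stopifnot(inherits(profile, "cnv_profile"), window >= 1L)
  lr <- profile$log2_ratio
  sm <- lr
  for (ch in unique(profile$bins$chrom)) {
    bi <- which(profile$bins$chrom == ch & profile$mask)
    if (length(bi) >= window) {
      for (j in seq_len(ncol(lr)))
        sm[bi, j] <- runmed(lr[bi, j], k = window, endrule = "median")
    }
  }
  calls <- matrix(NA_character_, nrow(lr), ncol(lr),
                  dimnames = dimnames(lr))
  calls[profile$mask, ] <- "neutral"
  calls[profile$mask & sm >= thresholds[2L]] <- "gain"
  calls[profile$mask & sm <= thresholds[1L]] <- "loss"
  # revert isolated single-bin calls, per chromosome
  for (ch in unique(profile$bins$chrom)) {
    bi <- which(profile$bins$chrom == ch)
    for (j in seq_len(ncol(calls))) {
      v <- calls[bi, j]
      r <- rle(v)
      single <- r$lengths == 1L & !is.na(r$values) & r$values != "neutral"
      if (any(single)) {
        r$values[single] <- "neutral"
        calls[bi, j] <- inverse.rle(r)
      }
    }
  }
  profile$log2_smooth <- sm
  profile$calls <- calls
  profile
}

#' Genome-altered burden
#'
#' Percentage of analysed genome length falling in bins called gained or
#' lost.
#'
#' @param profile A `cnv_profile` with calls (see [cnv_call()]).
#' @return Named numeric vector of burden percentages, one per sample,
#'   each in `[0, 100]`.
#' @export
cnv_burden <- function(profile) {
  stopifnot(!is.null(profile$calls))
  w <- profile$bins$end - profile$bins$start
  analysed <- sum(w[profile$mask])
  apply(profile$calls, 2L, function(v) {
    100 * sum(w[!is.na(v) & v != "neutral"]) / analysed
  })
}

#' Compare genome-altered burden between groups
#'
#' @param burden_a,burden_b Numeric burden vectors (percent) for the two
#'   groups.
#' @return [mann_whitney()] result plus the group medians.
#' @export
compare_burden <- function(burden_a, burden_b) {
  mw <- mann_whitney(burden_a, burden_b)
  c(mw, list(median_a = median(burden_a), median_b = median(burden_b)))
}
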