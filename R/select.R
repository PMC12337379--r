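#' Filtering thresholds for candidate DMR segments
#'
#' Candidate segments from the HMM are triaged on length, summed HMM
#' score, number of member CpGs and absolute between-group methylation
#' difference before statistical testing.
#'
#' @param min_length Minimum segment span in bp.
#' @param min_score Minimum summed per-site LLR in nats.
#' @param min_cpgs Minimum number of member CpG sites.
#' @param min_abs_delta_frac Minimum `|mean_frac_A - mean_frac_B|`.
#' @return List of class `filter_config`.
#' @export
filter_config <- function(min_length = 500, min_score = 20,
                          min_cpgs = 5L, min_abs_delta_frac = 0.2) {
  stopifnot(min_length >= 0, min_score >= 0, min_cpgs >= 0,
            min_abs_delta_frac >= 0)
  structure(list(min_length = min_length, min_score = min_score,
                 min_cpgs = as.integer(min_cpgs),
                 min_abs_delta_frac = min_abs_delta_frac),
            class = "filter_config")
}

#' Filter candidate segments
#'
#' Pure subset operation: a segment is kept iff it passes all four
#' thresholds of [filter_config()]; order is preserved.
#'
#' @param segs Segment table from [viterbi_segment()].
#' @param cfg A [filter_config()].
#' @return The surviving rows of `segs`.
#' @export
filter_segments <- function(segs, cfg = filter_config()) {
  if (nrow(segs) == 0L) return(segs)
  keep <- (segs$end - segs$start) >= cfg$min_length &
    segs$hmm_score >= cfg$min_score &
    segs$n_cpgs >= cfg$min_cpgs &
    abs(segs$delta_frac) >= cfg$min_abs_delta_frac
  segs[keep]
}

#' Per-sample segment methylation scores
#'
#' For each segment and sample, the coverage-weighted methylation score
#' `sum(n_mod) / sum(n_valid)` over the segment's member CpG sites that
#' pass the cohort coverage mask. Samples with no covered member site get
#' `NA`.
#'
#' @param segs Segment table (`chrom`, `start`, `end`, `segment_id`).
#' @param cm A `cohort_matrix`.
#' @return Numeric matrix segments x samples of scores in `[0, 1]`;
#'   attribute `"unscorable"` lists segment ids with no covered site in
#'   any sample.
#' @export
score_segments <- function(segs, cm) {
  n <- nrow(segs)
  ids <- if (n > 0L && "segment_id" %in% names(segs)) segs$segment_id
         else as.character(seq_len(n))
  out <- matrix(NA_real_, n, nrow(cm$samples),
                dimnames = list(ids, cm$samples$sample_id))
  if (n == 0L) return(out)
  modm <- cm$mod * cm$mask
  valm <- cm$valid * cm$mask
  for (i in seq_len(n)) {
    rows <- which(cm$sites$chrom == segs$chrom[i] &
                    cm$sites$start >= segs$start[i] &
                    cm$sites$start < segs$end[i])
    if (length(rows) == 0L) next
    tv <- colSums(valm[rows, , drop = FALSE])
    tm <- colSums(modm[rows, , drop = FALSE])
    out[i, ] <- ifelse(tv > 0, tm / tv, NA_real_)
  }
  unscorable <- ids[rowSums(!is.na(out)) == 0L]
  attr(out, "unscorable") <- unscorable
  out
}

#' Two-sided Mann-Whitney test between per-sample scores
#'
#' Exact null distribution when there are no ties and group sizes permit
#' (as for the 13-vs-8 cohort scale), tie-corrected normal approximation
#' otherwise (no continuity correction).
#'
#' @param a,b Numeric score vectors for the two groups (>= 2 values each).
#' @param alpha Selection threshold on the raw p-value (default 0.05).
#' @return List with `u_stat` (U for `a`), `p_value` and `selected`
#'   (`p_value < alpha`).
#' @export
mann_whitney <- function(a, b, alpha = 0.05) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (length(unique(c(a, b))) == 1L)
    return(list(u_stat = length(a) * length(b) / 2, p_value = 1,
                selected = FALSE))
  res <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", correct = FALSE))
  p <- min(unname(res$p.value), 1)
  list(u_stat = unname(res$statistic), p_value = p, selected = p < alpha)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' the input order is preserved.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Adjusted values in the original order.
#' @export
adjust_bh <- function(p) p.adjust(p, method = "BH")

#' Select high-confidence DMRs
#'
#' Runs the full triage: threshold filtering ([filter_segments()]),
#' per-sample scoring ([score_segments()]), a two-sided Mann-Whitney test
#' per segment between the two groups, and selection at raw `p < alpha`
#' with BH-adjusted values reported alongside.
#'
#' @param segs Candidate segments from [viterbi_segment()].
#' @param cm A `cohort_matrix`.
#' @param cfg A [filter_config()].
#' @param alpha Raw p-value threshold (default 0.05).
#' @param groups Optional group-label override (label permutation).
#' @param group_a,group_b The two group labels.
#' @return List with `table` (filtered segments plus `u_stat`, `p_value`,
#'   `p_adj_bh`, `selected`), `scores` (per-sample score matrix of the
#'   filtered segments) and `summary` (selected/hyper/hypo counts, genomic
#'   bp, mean lengths and mean `|delta_log2|` per direction).
#' @export
select_dmrs <- function(segs, cm, cfg = filter_config(), alpha = 0.05,
                        groups = NULL, group_a = "BC", group_b = "nonBC") {
  if (is.null(groups)) groups <- cm$samples$group
  filt <- filter_segments(segs, cfg)
  scores <- score_segments(filt, cm)
  ia <- groups == group_a
  ib <- groups == group_b
  n <- nrow(filt)
  u <- p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    va <- scores[i, ia]; va <- va[!is.na(va)]
    vb <- scores[i, ib]; vb <- vb[!is.na(vb)]
    if (length(va) < 2L || length(vb) < 2L) next
    mw <- mann_whitney(va, vb, alpha)
    u[i] <- mw$u_stat; p[i] <- mw$p_value
  }
  tab <- copy(filt)
  tab[, `:=`(u_stat = u, p_value = p, p_adj_bh = adjust_bh(p),
             selected = !is.na(p) & p < alpha)]
  sel <- tab[selected == TRUE]
  dirsum <- function(d) {
    s <- sel[direction == d]
    list(n = nrow(s), bp = sum(s$end - s$start),
         mean_length = if (nrow(s)) mean(s$end - s$start) else NA_real_,
         mean_abs_delta_log2 = if (nrow(s)) mean(abs(s$delta_log2))
                               else NA_real_)
  }
  hy <- dirsum("hyper"); ho <- dirsum("hypo")
  list(table = tab[], scores = scores,
       summary = list(n_candidates = nrow(segs), n_filtered = n,
                      n_selected = nrow(sel),
                      n_hyper = hy$n, n_hypo = ho$n,
                      bp_hyper = hy$bp, bp_hypo = ho$bp,
                      mean_length_hyper = hy$mean_length,
                      mean_length_hypo = ho$mean_length,
                      mean_abs_delta_log2_hyper = hy$mean_abs_delta_log2,
                      mean_abs_delta_log2_hypo = ho$mean_abs_delta_log2))
}
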