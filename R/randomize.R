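#' Label-permutation null for the DMR pipeline
#'
#' Re-runs the complete DMR identification pipeline — group pooling,
#' two-state HMM segmentation, threshold filtering and Mann-Whitney
#' selection, through the very same functions as the true analysis — on
#' random partitions of the cohort into pseudo-groups of the stated
#' sizes, recording the number of selected DMRs per permutation. A true
#' signal manifests as a true-label count far above the permutation
#' distribution.
#'
#' @param cm A `cohort_matrix`.
#' @param n_perm Number of label permutations (default 50).
#' @param sizes Integer vector `c(n_a, n_b)`: sizes of the pseudo-group-A
#'   and pseudo-group-B partitions. Defaults to the true group sizes.
#' @param seed Optional integer seed for the partition draws.
#' @param params An [hmm_params()].
#' @param cfg A [filter_config()].
#' @param alpha Selection threshold.
#' @param group_a,group_b True group labels.
#' @return List with `true_count`, `null_counts` (length `n_perm`),
#'   `null_median`, `null_max` and the drawn `partitions` (list of
#'   group-A sample-index vectors).
#' @export
permute_label_null <- function(cm, n_perm = 50L, sizes = NULL,
                               seed = NULL, params = hmm_params(),
                               cfg = filter_config(), alpha = 0.05,
                               group_a = "BC", group_b = "nonBC") {
  n <- nrow(cm$samples)
  if (is.null(sizes))
    sizes <- c(sum(cm$samples$group == group_a),
               sum(cm$samples$group == group_b))
  if (sum(sizes) != n)
    stop("sizes (", paste(sizes, collapse = "+"),
         ") do not sum to the cohort size (", n, ")")
  if (!is.null(seed)) set.seed(seed)
  run_count <- function(groups) {
    ev <- pool_evidence(cm, groups = groups, group_a = group_a,
                        group_b = group_b, eps = params$eps)
    segs <- viterbi_segment(ev, params)
    sel <- select_dmrs(segs, cm, cfg, alpha, groups = groups,
                       group_a = group_a, group_b = group_b)
    sel$summary$n_selected
  }
  true_count <- run_count(cm$samples$group)
  partitions <- lapply(seq_len(n_perm), function(i)
    sort(sample.int(n, sizes[1L])))
  null_counts <- vapply(partitions, function(a_idx) {
    g <- rep(group_b, n)
    g[a_idx] <- group_a
    run_count(g)
  }, numeric(1L))
  list(true_count = true_count, null_counts = null_counts,
       null_median = median(null_counts), null_max = max(null_counts),
       partitions = partitions)
}

#' Random-segment GSEA null
#'
#' Samples sets of `k` segments without replacement from the filtered
#' candidate-segment pool, aggregates gene deltas and runs preranked
#' GSEA for each set, counting the pathways called significant at the
#' dual threshold. When differential signal is confined to the true DMR
#' subset, random draws dilute it and the per-set significant-pathway
#' count collapses (median 0).
#'
#' @param pool Candidate-segment table (the filtered set), carrying
#'   `segment_id` and `delta_log2`.
#' @param calls Context calls for the pool from [classify_context()].
#' @param k Segments per random set (`k <= nrow(pool)`).
#' @param pathways Named list of gene sets.
#' @param n_sets Number of random sets (default 50).
#' @param n_perm GSEA permutations per set.
#' @param seed Optional integer master seed; per-set substream seeds are
#'   drawn from it.
#' @param ... Further arguments passed to [gsea_preranked()].
#' @return List with `counts` (significant pathways per set), `median`
#'   and `max`.
#' @export
random_segment_gsea_null <- function(pool, calls, k, pathways,
                                     n_sets = 50L, n_perm = 1000L,
                                     seed = NULL, ...) {
  if (k > nrow(pool)) stop("k (", k, ") exceeds pool size (", nrow(pool), ")")
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_sets)
  counts <- vapply(seq_len(n_sets), function(i) {
    set.seed(sub_seeds[i])
    idx <- sample.int(nrow(pool), k)
    deltas <- aggregate_gene_deltas(pool[idx], calls)
    if (nrow(deltas) == 0L) return(0)
    ranked <- setNames(deltas$delta, deltas$gene_id)
    res <- gsea_preranked(ranked, pathways, n_perm = n_perm,
                          seed = sub_seeds[i], ...)
    sum(res$significant)
  }, numeric(1L))
  list(counts = counts, median = median(counts), max = max(counts))
}
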