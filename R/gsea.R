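#' Aggregate DMR deltas to gene level
#'
#' For every gene associated with at least one DMR (promoter or gene
#' body), the gene delta is the mean `delta_log2` over its DMRs —
#' positive for promoter/body hypermethylation in group A. The returned
#' table is ordered by decreasing delta with lexicographic gene-id
#' tie-breaking, ready for preranked enrichment.
#'
#' @param dmrs Segment table carrying `segment_id` and `delta_log2`.
#' @param calls Context calls from [classify_context()] (uses
#'   `gene_ids`).
#' @return `data.table` with `gene_id`, `delta`, `n_dmrs`, ordered for
#'   ranking.
#' @export
aggregate_gene_deltas <- function(dmrs, calls) {
  tab <- merge(as.data.table(dmrs)[, .(segment_id, delta_log2)],
               as.data.table(calls)[, .(segment_id, gene_ids)],
               by = "segment_id")
  tab <- tab[gene_ids != ""]
  if (nrow(tab) == 0L)
    return(data.table(gene_id = character(), delta = numeric(),
                      n_dmrs = integer()))
  long <- tab[, .(gene_id = strsplit(gene_ids, ";", fixed = TRUE)[[1L]]),
              by = .(segment_id, delta_log2)]
  out <- long[, .(delta = mean(delta_log2), n_dmrs = .N), by = gene_id]
  out[order(-delta, gene_id)]
}

# Weighted Kolmogorov-Smirnov enrichment statistic.
# w: |delta|^p in rank order; idx: sorted hit positions; N: universe size.
# Returns es, the extremum position kind and index of the defining hit.
.es_stat <- function(w, idx, N) {
  nh <- length(idx)
  wh <- unname(w[idx])
  tot <- sum(wh)
  phit <- if (tot > 0) cumsum(wh) / tot else seq_len(nh) / nh
  dec <- (idx - seq_len(nh)) / (N - nh)       # misses before each hit
  after <- phit - dec                          # running sum just after hit
  before <- c(0, phit[-nh]) - dec              # just before each hit
  i_max <- which.max(after)
  i_min <- which.min(before)
  up <- after[i_max]; dn <- -before[i_min]
  if (abs(up - dn) < 1e-9)                     # tied extrema cancel out
    list(es = 0, hit = i_max, positive = TRUE)
  else if (up > dn)
    list(es = up, hit = i_max, positive = TRUE)
  else
    list(es = before[i_min], hit = i_min, positive = FALSE)
}

#' Enrichment score of one gene set on a ranked list
#'
#' Weighted Kolmogorov-Smirnov running-sum statistic (weight exponent
#' `p`, default 1): walking down the ranking, set hits increment the sum
#' proportionally to `|delta|^p` (normalised over hits) and misses
#' decrement it by `1/(N - Nh)`; the enrichment score is the signed
#' extremum, and the leading edge is the hits up to (or from, for
#' negative scores) the extremum.
#'
#' @param ranked Named numeric vector of gene deltas; sorted internally
#'   by decreasing delta with lexicographic tie-breaking.
#' @param gene_set Character vector of member genes.
#' @param p Weight exponent (default 1).
#' @return List with `es`, `leading_edge`, `n_hits`; `es = NA` and
#'   `empty = TRUE` when the set is disjoint from the ranking.
#' @export
enrichment_score <- function(ranked, gene_set, p = 1) {
  ord <- order(-ranked, names(ranked))
  ranked <- ranked[ord]
  N <- length(ranked)
  idx <- which(names(ranked) %in% gene_set)
  if (length(idx) == 0L)
    return(list(es = NA_real_, leading_edge = character(0), n_hits = 0L,
                empty = TRUE))
  if (length(idx) == N)
    return(list(es = 1, leading_edge = names(ranked), n_hits = N,
                empty = FALSE))
  st <- .es_stat(abs(ranked)^p, idx, N)
  le <- if (st$positive) names(ranked)[idx[seq_len(st$hit)]]
        else names(ranked)[idx[st$hit:length(idx)]]
  list(es = st$es, leading_edge = le, n_hits = length(idx),
       empty = FALSE)
}

#' Preranked gene-set enrichment with permutation null
#'
#' Runs [enrichment_score()] for every eligible pathway, builds a
#' gene-label permutation null (random hit positions, same set size and
#' weights), and reports sign-matched normalised enrichment scores and
#' permutation p-values with BH adjustment. A pathway is called
#' significant at the dual threshold `p_adj < alpha` and
#' `|NES| >= nes_threshold`.
#'
#' @param ranked Named numeric vector of gene deltas.
#' @param pathways Named list of gene sets (e.g. from [read_gmt()] or
#'   [simulate_pathways()]).
#' @param n_perm Number of permutations (default 1000); p-values are
#'   floored at `1/n_perm`.
#' @param seed Optional integer seed.
#' @param min_size,max_size Pathway eligibility bounds on the number of
#'   member genes present in the ranking.
#' @param p Weight exponent.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param nes_threshold NES magnitude threshold (default 1.5).
#' @return `data.table` with `pathway`, `es`, `nes`, `p_value`, `p_adj`,
#'   `size`, `leading_edge` (semicolon-joined) and `significant`.
#' @export
gsea_preranked <- function(ranked, pathways, n_perm = 1000L, seed = NULL,
                           min_size = 5L, max_size = 500L, p = 1,
                           alpha = 0.05, nes_threshold = 1.5) {
  if (!is.null(seed)) set.seed(seed)
  ord <- order(-ranked, names(ranked))
  ranked <- ranked[ord]
  N <- length(ranked)
  w <- abs(ranked)^p
  sizes <- vapply(pathways, function(s) sum(names(ranked) %in% s),
                  integer(1L))
  elig <- which(sizes >= min_size & sizes <= pmin(max_size, N - 1L))
  res <- vector("list", length(elig))
  for (j in seq_along(elig)) {
    pw <- elig[j]
    k <- sizes[pw]
    obs <- enrichment_score(ranked, pathways[[pw]], p = p)
    null_es <- vapply(seq_len(n_perm), function(i)
      .es_stat(w, sort(sample.int(N, k)), N)$es, numeric(1L))
    same <- if (obs$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    if (length(same) == 0L) {
      nes <- NA_real_
      pval <- 1 / n_perm
    } else {
      nes <- obs$es / mean(abs(same))
      pval <- max(sum(abs(same) >= abs(obs$es)), 1) / length(same)
      pval <- max(pval, 1 / n_perm)
    }
    res[[j]] <- data.table(
      pathway = names(pathways)[pw], es = obs$es, nes = nes,
      p_value = min(pval, 1), size = k,
      leading_edge = paste(obs$leading_edge, collapse = ";"))
  }
  if (length(res) == 0L)
    return(data.table(pathway = character(), es = numeric(),
                      nes = numeric(), p_value = numeric(),
                      p_adj = numeric(), size = integer(),
                      leading_edge = character(),
                      significant = logical()))
  out <- rbindlist(res)
  out[, p_adj := adjust_bh(p_value)]
  out[, significant := p_adj < alpha & !is.na(nes) &
        abs(nes) >= nes_threshold]
  data.table::setcolorder(out, c("pathway", "es", "nes", "p_value",
                                 "p_adj", "size", "leading_edge",
                                 "significant"))
  out[order(p_value, pathway)]
}
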