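# Independent brute-force oracles, kept free of the package's internal
# code paths: exhaustive path enumeration for the HMM, permutation
# enumeration for the rank test, and a literal running-sum for the
# enrichment score.

# score one complete state path (FALSE = Same, TRUE = Different) under the
# two-state model; e is the per-site Different emission log-score
oracle_path_score <- function(path, e, params) {
  s <- if (path[1]) log(1 - params$start_prob_same) + e[1]
       else log(params$start_prob_same)
  if (length(path) > 1) {
    for (i in 2:length(path)) {
      s <- s + if (!path[i - 1] && !path[i]) log(params$p_stay_same)
        else if (!path[i - 1] && path[i]) log(1 - params$p_stay_same)
        else if (path[i - 1] && path[i]) log(params$p_stay_diff)
        else log(1 - params$p_stay_diff)
      if (path[i]) s <- s + e[i]
    }
  }
  s
}

oracle_all_paths <- function(n) {
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  lapply(seq_len(nrow(grid)), function(i) unname(grid[i, ]))
}

# exhaustive MAP path over all 2^n paths
oracle_viterbi <- function(llr, params) {
  e <- llr - params$llr_threshold
  paths <- oracle_all_paths(length(llr))
  scores <- vapply(paths, oracle_path_score, numeric(1), e = e,
                   params = params)
  list(path = paths[[which.max(scores)]], score = max(scores))
}

# exhaustive forward-backward posterior P(Different) per site
oracle_posterior <- function(llr, params) {
  e <- llr - params$llr_threshold
  paths <- oracle_all_paths(length(llr))
  scores <- vapply(paths, oracle_path_score, numeric(1), e = e,
                   params = params)
  w <- exp(scores - max(scores))
  w <- w / sum(w)
  vapply(seq_along(llr), function(i)
    sum(w[vapply(paths, `[`, logical(1), i)]), numeric(1))
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
oracle_mw_p <- function(a, b) {
  vals <- c(a, b)
  n1 <- length(a)
  combs <- utils::combn(length(vals), n1)
  u_of <- function(idx) {
    x <- vals[idx]; y <- vals[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  u_all <- apply(combs, 2, u_of)
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# literal weighted KS running sum over the full ranking
oracle_es <- function(ranked, gene_set, p = 1) {
  ord <- order(-ranked, names(ranked))
  ranked <- ranked[ord]
  hit <- names(ranked) %in% gene_set
  w <- abs(ranked)^p
  nh <- sum(hit)
  wsum <- sum(w[hit])
  run <- numeric(length(ranked))
  cur <- 0
  for (i in seq_along(ranked)) {
    cur <- cur + if (hit[i]) {
      if (wsum > 0) w[i] / wsum else 1 / nh
    } else -1 / (length(ranked) - nh)
    run[i] <- cur
  }
  if (abs(max(run) + min(run)) < 1e-9) return(0)  # tied extrema
  unname(run[which.max(abs(run))])
}

# textbook Pearson chi-square on a contingency table
oracle_chisq <- function(tab) {
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - exp_tab)^2 / exp_tab)
}

random_evidence <- function(n, depth = 30) {
  tA <- rpois(n, depth) + 1L
  tB <- rpois(n, depth) + 1L
  pA <- runif(n); pB <- runif(n)
  data.table::data.table(
    chrom = "chr1", pos = cumsum(sample(50:500, n, replace = TRUE)),
    mA = rbinom(n, tA, pA), tA = tA, mB = rbinom(n, tB, pB), tB = tB)
}
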