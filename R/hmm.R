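#' Two-state HMM parameters for DMR segmentation
#'
#' The segmentation model assigns every CpG site to one of two hidden
#' states, "Same" (no between-group difference) or "Different"
#' (differentially methylated), so that spatially correlated methylation
#' changes are called as contiguous regions rather than isolated sites.
#'
#' @param p_stay_same Self-transition probability of the Same state.
#' @param p_stay_diff Self-transition probability of the Different state.
#' @param start_prob_same Start probability of the Same state (the chain
#'   also restarts with these probabilities after a break).
#' @param eps Pseudocount added to modified/valid counts when estimating
#'   per-group methylation rates for the log-likelihood ratio.
#' @param max_gap Maximum distance in bp between adjacent CpGs before the
#'   chain is broken; the HMM restarts rather than bridging CpG deserts.
#' @param llr_threshold Per-site evidence threshold in nats subtracted from
#'   the log-likelihood ratio when scoring the Different state. Under the
#'   no-difference null the LLR of a free-rate vs pooled-rate binomial
#'   comparison has positive expectation (~0.5 nats, half a 1-df
#'   chi-square), so scoring Different by the raw LLR would favour
#'   Different over arbitrarily long null stretches; the offset makes the
#'   Different state pay for itself only where per-site evidence exceeds
#'   ordinary sampling noise. Default 2 nats (~ the 95th percentile of the
#'   null LLR).
#' @return List of class `hmm_params`.
#' @export
hmm_params <- function(p_stay_same = 0.95, p_stay_diff = 0.90,
                       start_prob_same = 0.95, eps = 0.5,
                       max_gap = 1000L, llr_threshold = 2) {
  stopifnot(p_stay_same > 0, p_stay_same < 1,
            p_stay_diff > 0, p_stay_diff < 1,
            start_prob_same > 0, start_prob_same < 1,
            eps >= 0, max_gap > 0, llr_threshold >= 0)
  structure(list(p_stay_same = p_stay_same, p_stay_diff = p_stay_diff,
                 start_prob_same = start_prob_same, eps = eps,
                 max_gap = as.integer(max_gap),
                 llr_threshold = llr_threshold),
            class = "hmm_params")
}

#' Pool per-site counts by group
#'
#' Sums modified and valid counts over the unmasked samples of each group
#' at every CpG site and attaches the per-site log-likelihood ratio of
#' "Different" (free per-group rates) versus "Same" (one pooled rate).
#' Sites with zero pooled coverage in either group are dropped.
#'
#' @param cm A `cohort_matrix` from [build_cohort_matrix()].
#' @param groups Optional character vector overriding
#'   `cm$samples$group` (used by label permutation); must contain exactly
#'   the two labels `group_a` and `group_b`.
#' @param group_a,group_b Labels of the two groups; `group_a` is the
#'   cancer group whose elevation is reported as hypermethylation.
#' @param eps Pseudocount for the rate estimates (see [site_llr()]).
#' @return `data.table` with `chrom`, `pos`, `mA`, `tA`, `mB`, `tB`,
#'   `llr`, ordered by (chrom, pos).
#' @export
pool_evidence <- function(cm, groups = NULL, group_a = "BC",
                          group_b = "nonBC", eps = 0.5) {
  if (is.null(groups)) groups <- cm$samples$group
  a <- which(groups == group_a)
  b <- which(groups == group_b)
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must have >= 1 sample")
  modm <- cm$mod * cm$mask
  valm <- cm$valid * cm$mask
  ev <- data.table(
    chrom = cm$sites$chrom, pos = cm$sites$start,
    mA = as.integer(rowSums(modm[, a, drop = FALSE])),
    tA = as.integer(rowSums(valm[, a, drop = FALSE])),
    mB = as.integer(rowSums(modm[, b, drop = FALSE])),
    tB = as.integer(rowSums(valm[, b, drop = FALSE])))
  ev <- ev[tA > 0L & tB > 0L]
  ev[, llr := site_llr(mA, tA, mB, tB, eps = eps)]
  setorder(ev, chrom, pos)
  ev[]
}

# m*log(p) with the 0*log(0) = 0 convention
.xlogy <- function(m, p) ifelse(m == 0, 0, m * log(p))

.binom_ll <- function(m, t, p) .xlogy(m, p) + .xlogy(t - m, 1 - p)

#' Per-site log-likelihood ratio of differential methylation
#'
#' Binomial log-likelihood ratio (in nats) of the two-rate model (each
#' group at its own rate) against the single pooled-rate model:
#' `llr = [l(mA,tA;pA) + l(mB,tB;pB)] - [l(mA,tA;p) + l(mB,tB;p)]` with
#' `l(m,t;p) = m log p + (t-m) log(1-p)`, `pA = (mA+eps)/(tA+2eps)` (and
#' likewise `pB`, pooled `p`). Vectorised; non-negative up to the
#' pseudocount shrinkage.
#'
#' @param mA,tA Modified and valid counts pooled over group A.
#' @param mB,tB Counts pooled over group B.
#' @param eps Pseudocount (default 0.5).
#' @return Numeric vector of LLRs in nats, clipped at 0.
#' @export
site_llr <- function(mA, tA, mB, tB, eps = 0.5) {
  stopifnot(all(tA > 0), all(tB > 0))
  pA <- (mA + eps) / (tA + 2 * eps)
  pB <- (mB + eps) / (tB + 2 * eps)
  p0 <- (mA + mB + eps) / (tA + tB + 2 * eps)
  llr <- .binom_ll(mA, tA, pA) + .binom_ll(mB, tB, pB) -
    .binom_ll(mA, tA, p0) - .binom_ll(mB, tB, p0)
  pmax(llr, 0)
}

# split ordered evidence into chains broken at chromosome boundaries and
# gaps > max_gap; returns an integer chain id per row
.chain_ids <- function(ev, max_gap) {
  if (nrow(ev) == 0L) return(integer(0))
  new_chain <- c(TRUE, ev$chrom[-1L] != ev$chrom[-nrow(ev)] |
                   ev$pos[-1L] - ev$pos[-nrow(ev)] > max_gap)
  cumsum(new_chain)
}

# emission log-scores: Same = 0, Different = llr - llr_threshold
.emissions <- function(llr, params) llr - params$llr_threshold

#' Viterbi segmentation of differential methylation
#'
#' Computes the maximum a posteriori state path of the two-state HMM over
#' ordered site evidence and emits maximal runs of the Different state as
#' candidate DMR segments. Chains are broken at chromosome boundaries and
#' at gaps larger than `max_gap`, where the path restarts at the start
#' probabilities. Ties are resolved towards Same (deterministic).
#'
#' @param evidence Output of [pool_evidence()], ordered by (chrom, pos).
#' @param params An [hmm_params()].
#' @param delta_eps Pseudo-fraction added to both group means when forming
#'   `delta_log2` (default 0.01).
#' @return `data.table` of segments: `segment_id`, `chrom`, `start`, `end`
#'   (half-open, first to last member CpG + 1), `n_cpgs`, `hmm_score`
#'   (summed member LLR, nats), `mean_frac_A`, `mean_frac_B` (pooled-count
#'   fractions), `delta_frac`, `delta_log2` and `direction`
#'   (`hyper`/`hypo` with respect to group A).
#' @export
viterbi_segment <- function(evidence, params = hmm_params(),
                            delta_eps = 0.01) {
  empty <- data.table(
    segment_id = character(), chrom = character(), start = integer(),
    end = integer(), n_cpgs = integer(), hmm_score = numeric(),
    mean_frac_A = numeric(), mean_frac_B = numeric(),
    delta_frac = numeric(), delta_log2 = numeric(), direction = character())
  if (is.null(evidence) || nrow(evidence) == 0L) return(empty)
  chain <- .chain_ids(evidence, params$max_gap)
  e <- .emissions(evidence$llr, params)
  state <- logical(nrow(evidence))  # TRUE = Different
  for (cid in unique(chain)) {
    idx <- which(chain == cid)
    state[idx] <- .viterbi_chain(e[idx], params)
  }
  segs <- .states_to_segments(evidence, state, chain, delta_eps)
  if (nrow(segs) == 0L) empty else segs
}

.viterbi_chain <- function(e, params) {
  n <- length(e)
  lss <- log(params$p_stay_same); lsd <- log(1 - params$p_stay_same)
  ldd <- log(params$p_stay_diff); lds <- log(1 - params$p_stay_diff)
  vS <- log(params$start_prob_same)
  vD <- log(1 - params$start_prob_same) + e[1L]
  fromS <- matrix(FALSE, 2L, n)  # [state, i]: TRUE if best predecessor Same
  if (n > 1L) {
    for (i in 2:n) {
      aS <- vS + lss; bS <- vD + lds
      aD <- vS + lsd; bD <- vD + ldd
      if (aS >= bS) { nS <- aS; fromS[1L, i] <- TRUE } else nS <- bS
      if (aD >= bD) { nD <- aD + e[i]; fromS[2L, i] <- TRUE }
      else nD <- bD + e[i]
      vS <- nS; vD <- nD
    }
  }
  path <- logical(n)
  cur <- vD > vS  # TRUE = Different; tie -> Same
  path[n] <- cur
  if (n > 1L) {
    for (i in n:2) {
      cur <- !fromS[if (cur) 2L else 1L, i]
      path[i - 1L] <- cur
    }
  }
  path
}

.states_to_segments <- function(evidence, state, chain, delta_eps) {
  if (!any(state)) return(data.table())
  # runs never span chain breaks, even when both sides are Different
  run_id <- cumsum(c(TRUE, state[-1L] != state[-length(state)] |
                       chain[-1L] != chain[-length(chain)]))
  r <- list(lengths = rle(run_id)$lengths,
            values = state[!duplicated(run_id)])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  segs <- rbindlist(lapply(keep, function(k) {
    i <- starts[k]:ends[k]
    sub <- evidence[i]
    mfA <- sum(sub$mA) / sum(sub$tA)
    mfB <- sum(sub$mB) / sum(sub$tB)
    data.table(chrom = sub$chrom[1L], start = sub$pos[1L],
               end = sub$pos[nrow(sub)] + 1L, n_cpgs = nrow(sub),
               hmm_score = sum(sub$llr), mean_frac_A = mfA,
               mean_frac_B = mfB, delta_frac = mfA - mfB,
               delta_log2 = log2((mfA + delta_eps) / (mfB + delta_eps)),
               direction = if (mfA - mfB > 0) "hyper" else "hypo")
  }))
  setorder(segs, chrom, start)
  segs[, segment_id := sprintf("dmr_%05d", .I)]
  data.table::setcolorder(segs, "segment_id")
  segs[]
}

#' Forward-backward posterior probability of the Different state
#'
#' Diagnostic companion to [viterbi_segment()]: the marginal posterior
#' P(Different) at every site under the same emissions, transitions and
#' chain-break semantics.
#'
#' @inheritParams viterbi_segment
#' @return Numeric vector, one posterior per evidence row.
#' @export
posterior_scores <- function(evidence, params = hmm_params()) {
  if (is.null(evidence) || nrow(evidence) == 0L) return(numeric(0))
  chain <- .chain_ids(evidence, params$max_gap)
  e <- .emissions(evidence$llr, params)
  post <- numeric(nrow(evidence))
  for (cid in unique(chain)) {
    idx <- which(chain == cid)
    post[idx] <- .fb_chain(e[idx], params)
  }
  post
}

.lse2 <- function(a, b) {
  m <- pmax(a, b)
  m + log1p(exp(pmin(a, b) - m))
}

.fb_chain <- function(e, params) {
  n <- length(e)
  lss <- log(params$p_stay_same); lsd <- log(1 - params$p_stay_same)
  ldd <- log(params$p_stay_diff); lds <- log(1 - params$p_stay_diff)
  fS <- numeric(n); fD <- numeric(n)
  fS[1L] <- log(params$start_prob_same)
  fD[1L] <- log(1 - params$start_prob_same) + e[1L]
  if (n > 1L) for (i in 2:n) {
    fS[i] <- .lse2(fS[i - 1L] + lss, fD[i - 1L] + lds)
    fD[i] <- .lse2(fS[i - 1L] + lsd, fD[i - 1L] + ldd) + e[i]
  }
  bS <- numeric(n); bD <- numeric(n)
  if (n > 1L) for (i in (n - 1L):1L) {
    bS[i] <- .lse2(lss + bS[i + 1L], lsd + e[i + 1L] + bD[i + 1L])
    bD[i] <- .lse2(lds + bS[i + 1L], ldd + e[i + 1L] + bD[i + 1L])
  }
  lpS <- fS + bS
  lpD <- fD + bD
  1 / (1 + exp(lpS - lpD))
}
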