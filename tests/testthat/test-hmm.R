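test_that("evidence pooling sums counts within groups and drops one-sided sites", {
  mk <- function(id, grp, starts, nm, nv)
    sample_methylome(data.table::data.table(
      chrom = "chr1", start = starts, end = starts + 1L, strand = ".",
      n_mod = nm, n_valid = nv), id, grp)
  a1 <- mk("a1", "BC", c(10L, 50L), c(3L, 1L), c(10L, 4L))
  a2 <- mk("a2", "BC", 10L, 2L, 5L)
  b1 <- mk("b1", "nonBC", 10L, 1L, 8L)
  b2 <- mk("b2", "nonBC", 10L, 0L, 2L)
  cm <- build_cohort_matrix(list(a1, a2, b1, b2), min_cov = 1L)
  ev <- pool_evidence(cm)
  # site 50 covered only in BC: dropped
  expect_equal(ev$pos, 10L)
  expect_equal(ev$mA, 5L)   # 3 + 2
  expect_equal(ev$tA, 15L)  # 10 + 5
  expect_equal(ev$mB, 1L)
  expect_equal(ev$tB, 10L)
  expect_error(pool_evidence(cm, groups = rep("BC", 4)), "group")
})

test_that("pooled evidence matches a hand-pooled table on a 10-site fixture", {
  cm <- toy_cohort(n_sites = 10L, n_a = 2L, n_b = 2L, seed = 123L)
  ev <- pool_evidence(cm)
  ia <- cm$samples$group == "BC"
  for (i in seq_len(nrow(ev))) {
    row <- which(cm$sites$start == ev$pos[i])
    expect_equal(ev$mA[i], sum((cm$mod * cm$mask)[row, ia]))
    expect_equal(ev$tB[i], sum((cm$valid * cm$mask)[row, !ia]))
  }
})

test_that("site LLR has its closed forms", {
  # equal rates: zero evidence
  expect_equal(site_llr(5, 10, 10, 20, eps = 0), 0)
  expect_equal(site_llr(0, 10, 0, 7, eps = 0), 0)
  # complete separation 10/10 vs 0/10: -20 ln(1/2)
  expect_equal(site_llr(10, 10, 0, 10, eps = 0), -20 * log(0.5),
               tolerance = 1e-12)
})

test_that("site LLR agrees with an independent dbinom formulation", {
  set.seed(31)
  for (i in 1:50) {
    tA <- sample(1:50, 1); tB <- sample(1:50, 1)
    mA <- sample(0:tA, 1); mB <- sample(0:tB, 1)
    eps <- sample(c(0.5, 1), 1)
    pA <- (mA + eps) / (tA + 2 * eps)
    pB <- (mB + eps) / (tB + 2 * eps)
    p0 <- (mA + mB + eps) / (tA + tB + 2 * eps)
    ref <- dbinom(mA, tA, pA, log = TRUE) + dbinom(mB, tB, pB, log = TRUE) -
      dbinom(mA, tA, p0, log = TRUE) - dbinom(mB, tB, p0, log = TRUE)
    expect_equal(site_llr(mA, tA, mB, tB, eps = eps), max(ref, 0),
                 tolerance = 1e-9)
  }
})

test_that("zero-evidence input produces zero segments", {
  ev <- data.table::data.table(chrom = "chr1", pos = seq(0, 900, 100),
                               mA = 5L, tA = 10L, mB = 5L, tB = 10L)
  ev[, llr := 0]
  expect_equal(nrow(viterbi_segment(ev)), 0L)
  expect_equal(nrow(viterbi_segment(ev[0])), 0L)
})

test_that("Viterbi matches exhaustive path enumeration on small instances", {
  set.seed(17)
  params <- hmm_params()
  for (rep in 1:40) {
    n <- sample(1:10, 1)
    ev <- random_evidence(n)
    ev[, llr := site_llr(mA, tA, mB, tB, eps = params$eps)]
    oracle <- oracle_viterbi(ev$llr, params)
    segs <- viterbi_segment(ev, params)
    called <- rep(FALSE, n)
    for (j in seq_len(nrow(segs)))
      called[ev$pos >= segs$start[j] & ev$pos < segs$end[j]] <- TRUE
    expect_identical(called, oracle$path)
  }
})

test_that("posteriors match exhaustive enumeration on small instances", {
  set.seed(19)
  params <- hmm_params()
  for (rep in 1:25) {
    n <- sample(1:10, 1)
    ev <- random_evidence(n)
    ev[, llr := site_llr(mA, tA, mB, tB, eps = params$eps)]
    expect_equal(posterior_scores(ev, params),
                 oracle_posterior(ev$llr, params), tolerance = 1e-9)
  }
})

test_that("flat evidence with symmetric transitions gives the stationary posterior", {
  params <- hmm_params(p_stay_same = 0.8, p_stay_diff = 0.8,
                       start_prob_same = 0.5, llr_threshold = 0)
  ev <- data.table::data.table(chrom = "chr1", pos = seq(0, 1900, 100),
                               mA = 0L, tA = 10L, mB = 0L, tB = 10L,
                               llr = 0)
  expect_equal(posterior_scores(ev, params), rep(0.5, 20), tolerance = 1e-12)
})

test_that("single-site posterior is start-probability times emission", {
  params <- hmm_params()
  ev <- data.table::data.table(chrom = "chr1", pos = 0L, mA = 9L, tA = 10L,
                               mB = 1L, tB = 10L)
  ev[, llr := site_llr(mA, tA, mB, tB, eps = params$eps)]
  e <- ev$llr - params$llr_threshold
  wS <- params$start_prob_same
  wD <- (1 - params$start_prob_same) * exp(e)
  expect_equal(posterior_scores(ev, params), wD / (wS + wD),
               tolerance = 1e-12)
})

test_that("chains break across large gaps and chromosomes", {
  params <- hmm_params(max_gap = 1000L)
  block <- function(start, chrom = "chr1") data.table::data.table(
    chrom = chrom, pos = start + seq(0, 400, 100), mA = 20L, tA = 20L,
    mB = 0L, tB = 20L)
  ev <- rbind(block(0), block(5000))
  ev[, llr := site_llr(mA, tA, mB, tB)]
  segs <- viterbi_segment(ev, params)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$start, c(0L, 5000L))
  expect_equal(segs$n_cpgs, c(5L, 5L))
  # same layout on two chromosomes: also two segments
  ev2 <- rbind(block(0), block(200, "chr2"))
  data.table::setorder(ev2, chrom, pos)
  ev2[, llr := site_llr(mA, tA, mB, tB)]
  expect_equal(nrow(viterbi_segment(ev2, params)), 2L)
})

test_that("segment fields are computed from member sites", {
  ev <- data.table::data.table(
    chrom = "chr1", pos = c(0L, 100L, 200L),
    mA = c(18L, 20L, 19L), tA = 20L, mB = c(1L, 0L, 2L), tB = 20L)
  ev[, llr := site_llr(mA, tA, mB, tB)]
  segs <- viterbi_segment(ev)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$start, 0L)
  expect_equal(segs$end, 201L)
  expect_equal(segs$n_cpgs, 3L)
  expect_equal(segs$hmm_score, sum(ev$llr))
  expect_equal(segs$mean_frac_A, 57 / 60)
  expect_equal(segs$mean_frac_B, 3 / 60)
  expect_equal(segs$delta_frac, 54 / 60)
  expect_equal(segs$direction, "hyper")
  expect_equal(segs$delta_log2,
               log2((57 / 60 + 0.01) / (3 / 60 + 0.01)))
})

test_that("raising one site's evidence never flips it out of Different", {
  set.seed(23)
  params <- hmm_params()
  for (rep in 1:10) {
    n <- 8L
    ev <- random_evidence(n)
    ev[, llr := site_llr(mA, tA, mB, tB)]
    j <- sample(n, 1)
    in_diff <- function(e) {
      segs <- viterbi_segment(e, params)
      any(segs$start <= e$pos[j] & segs$end > e$pos[j])
    }
    base <- in_diff(ev)
    ev2 <- data.table::copy(ev)
    ev2$llr[j] <- ev2$llr[j] + 5
    if (base) expect_true(in_diff(ev2))
  }
})
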