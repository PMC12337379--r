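# Shared fixtures. The default-scale cohort is expensive (~10 s), so the
# acceptance tests build it once per session through a memoising accessor.

.fixture_env <- new.env(parent = emptyenv())

# small two-chromosome cohort for unit tests (seconds)
small_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- sim_config(chrom_sizes = c(chr1 = 2e6, chr2 = 2e6),
                      n_genes = 40L, n_hyper = 8L, n_hypo = 10L)
    ann <- simulate_annotation(cfg, seed = 401L)
    sim <- simulate_cohort(cfg, ann, seed = 402L)
    cm <- build_cohort_matrix(sim$methylomes)
    .fixture_env$small <- list(cfg = cfg, ann = ann, sim = sim, cm = cm)
  }
  .fixture_env$small
}

# full default-scale study cohort used by the acceptance suite
study_cohort <- function() {
  if (is.null(.fixture_env$study)) {
    cfg <- sim_config()
    ann <- simulate_annotation(cfg, seed = 201L)
    sim <- simulate_cohort(cfg, ann, seed = 202L)
    cm <- build_cohort_matrix(sim$methylomes)
    segs <- viterbi_segment(pool_evidence(cm))
    sel <- select_dmrs(segs, cm)
    pw <- simulate_pathways(cfg, ann, sim$truth, seed = 203L)
    .fixture_env$study <- list(cfg = cfg, ann = ann, sim = sim, cm = cm,
                               segments = segs, selection = sel,
                               pathways = pw)
  }
  .fixture_env$study
}

# tiny hand-sized cohort built record-by-record
toy_cohort <- function(n_sites = 20L, n_a = 3L, n_b = 3L, depth = 10L,
                       seed = 99L) {
  set.seed(seed)
  pos <- sort(sample.int(5000L, n_sites))
  mk <- function(id, grp) {
    nv <- rep(depth, n_sites)
    sample_methylome(
      data.table::data.table(chrom = "chr1", start = pos, end = pos + 1L,
                             strand = ".", n_mod = rbinom(n_sites, nv, 0.5),
                             n_valid = nv),
      id, grp, "high", 0)
  }
  ms <- c(lapply(seq_len(n_a), function(i) mk(paste0("A", i), "BC")),
          lapply(seq_len(n_b), function(i) mk(paste0("B", i), "nonBC")))
  build_cohort_matrix(ms, min_cov = 1L)
}
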