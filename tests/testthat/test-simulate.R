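test_that("annotation generation is seed-deterministic and well-formed", {
  cfg <- sim_config(chrom_sizes = c(chr1 = 2e6), n_genes = 20L)
  a1 <- simulate_annotation(cfg, seed = 5)
  a2 <- simulate_annotation(cfg, seed = 5)
  expect_identical(a1, a2)
  # intervals inside chromosome bounds, half-open
  expect_true(all(a1$genes$start >= 0 & a1$genes$end <= 2e6))
  expect_true(all(a1$repeats$start < a1$repeats$end))
  # every promoter window holds a CpG island
  for (i in seq_len(nrow(a1$genes))) {
    g <- a1$genes[i]
    n <- sum(a1$cpg$chrom == g$chrom &
               a1$cpg$pos >= g$tss - cfg$promoter_window &
               a1$cpg$pos < g$tss + cfg$promoter_window)
    expect_gte(n, 10L)
  }
})

test_that("zero genes yields a repeats-only annotation", {
  cfg <- sim_config(chrom_sizes = c(chr1 = 1e6), n_genes = 0L,
                    n_hyper = 0L, n_hypo = 0L)
  ann <- simulate_annotation(cfg, seed = 6)
  expect_equal(nrow(ann$genes), 0L)
  expect_gt(nrow(ann$repeats), 0L)
})

test_that("repeats tile roughly half of intergenic space", {
  ann <- small_cohort()$ann
  cfg <- small_cohort()$cfg
  rep_bp <- sum(ann$repeats$end - ann$repeats$start)
  gene_bp <- sum(ann$genes$end - ann$genes$start)
  intergenic_bp <- sum(cfg$chrom_sizes) - gene_bp
  frac <- rep_bp / intergenic_bp
  expect_gt(frac, 0.40)
  expect_lt(frac, 0.65)
})

test_that("cohort simulation is seed-deterministic", {
  cfg <- sim_config(chrom_sizes = c(chr1 = 1e6), n_genes = 15L,
                    n_hyper = 3L, n_hypo = 3L, n_bc = 3L, n_nonbc = 2L)
  ann <- simulate_annotation(cfg, seed = 8)
  s1 <- simulate_cohort(cfg, ann, seed = 9)
  s2 <- simulate_cohort(cfg, ann, seed = 9)
  expect_identical(s1$truth, s2$truth)
  expect_identical(lapply(s1$methylomes, `[[`, "records"),
                   lapply(s2$methylomes, `[[`, "records"))
})

test_that("non-cancer samples sit at the normal baseline", {
  sim <- small_cohort()$sim
  cfg <- small_cohort()$cfg
  # inside a planted hyper interval the nonBC group must stay low
  hy <- sim$truth$planted_hyper[1]
  fr <- unlist(lapply(sim$methylomes, function(m) {
    if (m$group != "nonBC") return(NULL)
    r <- m$records[chrom == hy$chrom & start >= hy$start & start < hy$end]
    sum(r$n_mod) / sum(r$n_valid)
  }))
  expect_lt(mean(fr), cfg$baseline_promoter + 0.15)
})

test_that("undiluted tumour recovers the planted level within 3 SE", {
  cfg <- sim_config(chrom_sizes = c(chr1 = 2e6), n_genes = 25L,
                    n_hyper = 4L, n_hypo = 2L, n_bc = 6L, n_nonbc = 2L,
                    tf_range = c(1, 1), depth_high = 30, noise_sd = 0.1)
  ann <- simulate_annotation(cfg, seed = 21)
  sim <- simulate_cohort(cfg, ann, seed = 22)
  hy <- sim$truth$planted_hyper[1]
  mods <- valids <- 0
  for (m in sim$methylomes) {
    if (m$group != "BC") next
    r <- m$records[chrom == hy$chrom & start >= hy$start & start < hy$end]
    mods <- mods + sum(r$n_mod); valids <- valids + sum(r$n_valid)
  }
  obs <- mods / valids
  se <- sqrt(cfg$hyper_level * (1 - cfg$hyper_level) / valids)
  # logit noise adds region-level spread beyond the binomial SE
  expect_lt(abs(obs - cfg$hyper_level), 3 * se + 0.05)
})

test_that("observed methylation is linear in tumour fraction", {
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  means <- vapply(grid, function(tf) {
    cfg <- sim_config(chrom_sizes = c(chr1 = 2e6), n_genes = 25L,
                      n_hyper = 4L, n_hypo = 2L, n_bc = 4L, n_nonbc = 2L,
                      tf_range = c(tf, tf), depth_high = 30)
    ann <- simulate_annotation(cfg, seed = 31)
    sim <- simulate_cohort(cfg, ann, seed = 32)
    hy <- sim$truth$planted_hyper[1]
    mods <- valids <- 0
    for (m in sim$methylomes) {
      if (m$group != "BC") next
      r <- m$records[chrom == hy$chrom & start >= hy$start & start < hy$end]
      mods <- mods + sum(r$n_mod); valids <- valids + sum(r$n_valid)
    }
    mods / valids
  }, numeric(1))
  fit <- lm(means ~ grid)
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("truth ledger intervals carry enough CpGs and do not overlap", {
  truth <- small_cohort()$sim$truth
  ann <- small_cohort()$ann
  cfg <- small_cohort()$cfg
  planted <- rbind(truth$planted_hyper[, .(chrom, start, end)],
                   truth$planted_hypo[, .(chrom, start, end)])
  for (i in seq_len(nrow(planted))) {
    n <- sum(ann$cpg$chrom == planted$chrom[i] &
               ann$cpg$pos >= planted$start[i] &
               ann$cpg$pos < planted$end[i])
    expect_gte(n, cfg$min_cpgs_planted)
  }
  data.table::setorder(planted, chrom, start)
  same <- planted$chrom[-1] == planted$chrom[-nrow(planted)]
  expect_true(all(planted$start[-1][same] >=
                    planted$end[-nrow(planted)][same]))
  expect_true(all(truth$samples[group == "nonBC", tumour_fraction] == 0))
})

test_that("CNV count simulation follows the admixture dilution model", {
  bins <- make_bins(c(chr1 = 10e6), 500e3)
  cfg <- sim_config(cnv_reads_per_mb = 4000,
                    cnv_intervals = data.table::data.table(
                      chrom = "chr1", start = 0L, end = 5e6, copy = 4L))
  mk_truth <- function(tf, copy) {
    cfg$cnv_intervals$copy <- copy
    list(truth = list(samples = data.table::data.table(
      sample_id = "s", group = "BC", tier = "low", tumour_fraction = tf),
      planted_cnv = cfg$cnv_intervals), cfg = cfg)
  }
  # tf = 0: flat profile
  t0 <- mk_truth(0, 4L)
  c0 <- simulate_cnv_counts(t0$cfg, t0$truth, bins, seed = 3)
  expect_lt(diff(range(tapply(c0[, 1], bins$start < 5e6, mean))) /
              mean(c0[, 1]), 0.05)
  # tf = 1, copy 4: ratio 2 between altered and neutral bins
  t1 <- mk_truth(1, 4L)
  c1 <- simulate_cnv_counts(t1$cfg, t1$truth, bins, seed = 4)
  ratio <- mean(c1[bins$start < 5e6, 1]) / mean(c1[bins$start >= 5e6, 1])
  expect_lt(abs(ratio - 2), 0.1)
  # tf = 0.5, homozygous loss: ratio 0.5
  t2 <- mk_truth(0.5, 0L)
  c2 <- simulate_cnv_counts(t2$cfg, t2$truth, bins, seed = 5)
  ratio2 <- mean(c2[bins$start < 5e6, 1]) / mean(c2[bins$start >= 5e6, 1])
  expect_lt(abs(ratio2 - 0.5), 0.05)
  expect_error(simulate_cnv_counts(cfg, t2$truth, rbind(bins, bins[1])),
               "overlap")
})

test_that("pathway simulation plants a known enriched set", {
  fx <- small_cohort()
  pw <- simulate_pathways(fx$cfg, fx$ann, fx$sim$truth, seed = 41)
  expect_length(pw$sets, fx$cfg$n_pathways)
  planted_genes <- fx$sim$truth$planted_hyper$gene_id
  planted_genes <- planted_genes[!is.na(planted_genes)]
  expect_identical(sort(pw$planted_overlap),
                   sort(intersect(pw$sets[[pw$enriched]], planted_genes)))
  expect_equal(length(pw$planted_overlap),
               min(round(fx$cfg$enriched_frac *
                           length(pw$sets[[pw$enriched]])),
                   length(planted_genes)))
  # determinism
  pw2 <- simulate_pathways(fx$cfg, fx$ann, fx$sim$truth, seed = 41)
  expect_identical(pw, pw2)
  # enrichment fraction 0: all sets plain uniform draws, still valid GMT
  cfg0 <- fx$cfg; cfg0$enriched_frac <- 0
  pw0 <- simulate_pathways(cfg0, fx$ann, fx$sim$truth, seed = 42)
  expect_length(pw0$sets, 50L)
  expect_true(all(unlist(pw0$sets) %in% fx$ann$genes$gene_id))
})

test_that("depth thinning preserves the methylation state", {
  m <- small_cohort()$sim$methylomes[[1]]
  thin <- thin_methylome(m, 0.2, seed = 50)
  expect_true(all(thin$records$n_mod <= thin$records$n_valid))
  expect_lt(abs(mean(thin$records$n_valid) - 0.2 * mean(m$records$n_valid)),
            0.5)
  merged <- merge(m$records[, .(chrom, start, f1 = frac)],
                  thin$records[n_valid >= 5, .(chrom, start, f2 = frac)],
                  by = c("chrom", "start"))
  expect_gt(cor(merged$f1, merged$f2), 0.5)
})
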