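toy_ann <- function() {
  genes <- data.table::data.table(
    gene_id = c("gX", "gY"), chrom = "chr1",
    start = c(10000L, 40000L), end = c(20000L, 52000L),
    strand = c("+", "+"), tss = c(10000L, 40000L))
  exons <- data.table::data.table(
    gene_id = c("gX", "gX", "gY"), chrom = "chr1",
    start = c(10000L, 15000L, 40000L), end = c(10500L, 15400L, 40300L))
  structure(list(
    chrom_sizes = c(chr1 = 100000L), genes = genes, exons = exons,
    repeats = data.table::data.table(chrom = "chr1", start = 60000L,
                                     end = 70000L),
    cpg = data.table::data.table(chrom = character(), pos = integer()),
    promoter_window = 3000L), class = "genome_annotation")
}

test_that("context classification follows promoter > exon > intron > intergenic", {
  ann <- toy_ann()
  segs <- data.table::data.table(
    segment_id = c("d1", "d2", "d3", "d4", "d5"),
    chrom = "chr1",
    start = c(11000L,  # 1 kb downstream of gX TSS -> promoter window
              15100L,  # inside gX exon 2 -> exonic
              16000L,  # gX body, no exon -> intronic
              80000L,  # open space -> intergenic
              38500L), # overlaps gY promoter AND gX nothing -> promoter
    end = c(11200L, 15300L, 16500L, 81000L, 39000L))
  calls <- classify_context(segs, ann)
  expect_equal(calls$class,
               c("promoter", "exonic", "intronic", "intergenic", "promoter"))
  expect_equal(calls$gene_ids[1], "gX")
  expect_equal(calls$gene_ids[5], "gY")
  expect_equal(calls$gene_ids[4], "")
  # a segment overlapping gX's exon and gY's promoter window is promoter
  seg <- data.table::data.table(segment_id = "d6", chrom = "chr1",
                                start = 19500L, end = 37500L)
  call <- classify_context(seg, ann)
  expect_equal(call$class, "promoter")
  expect_true(grepl("gY", call$gene_ids))
  expect_error(classify_context(
    data.table::data.table(segment_id = "z", chrom = "chrZ",
                           start = 1L, end = 2L), ann), "chromosome")
})

test_that("classification agrees with brute-force interval checks", {
  ann <- small_cohort()$ann
  set.seed(91)
  n <- 100L
  ch <- sample(names(ann$chrom_sizes), n, replace = TRUE)
  st <- vapply(ch, function(c0)
    sample.int(ann$chrom_sizes[[c0]] - 5000L, 1L), integer(1))
  segs <- data.table::data.table(segment_id = sprintf("r%03d", 1:n),
                                 chrom = ch, start = st,
                                 end = st + sample(200:5000, n, TRUE))
  calls <- classify_context(segs, ann)
  overlaps <- function(s, iv)
    any(iv$chrom == s$chrom & iv$start < s$end & iv$end > s$start)
  for (i in seq_len(n)) {
    s <- segs[i]
    prom <- data.table::data.table(
      chrom = ann$genes$chrom,
      start = pmax(0L, ann$genes$tss - ann$promoter_window),
      end = ann$genes$tss + ann$promoter_window)
    expected <- if (overlaps(s, prom)) "promoter"
      else if (overlaps(s, ann$exons)) "exonic"
      else if (overlaps(s, ann$genes)) "intronic"
      else "intergenic"
    expect_equal(calls$class[i], expected, label = s$segment_id)
  }
  # exhaustive: every segment gets exactly one class
  expect_equal(sum(table(calls$class)), n)
})

test_that("context enrichment reproduces the hand-computed 2x2 example", {
  class <- rep(c("promoter", "other"), times = c(40, 40))
  direction <- c(rep("hyper", 30), rep("hypo", 10),
                 rep("hyper", 10), rep("hypo", 30))
  enr <- context_enrichment(class, direction)
  expect_equal(enr$chisq, 20, tolerance = 1e-12)
  expect_equal(enr$promoter_or, 9)
  expect_equal(enr$chisq, oracle_chisq(enr$table), tolerance = 1e-12)
  # identical distributions: statistic near zero
  enr0 <- context_enrichment(rep(c("promoter", "other"), 20),
                             rep(c("hyper", "hypo"), each = 20))
  expect_lt(enr0$chisq, 1e-10)
})

test_that("chi-square matches the textbook formula on random 4x2 tables", {
  set.seed(93)
  classes <- c("promoter", "exonic", "intronic", "intergenic")
  for (rep in 1:10) {
    cls <- sample(classes, 200, replace = TRUE, prob = runif(4) + 0.2)
    dir <- sample(c("hyper", "hypo"), 200, replace = TRUE)
    enr <- context_enrichment(cls, dir)
    expect_equal(enr$chisq, oracle_chisq(enr$table), tolerance = 1e-9)
  }
})

test_that("repeat content is exact interval arithmetic", {
  reps <- data.table::data.table(chrom = "chr1",
                                 start = c(0L, 500L), end = c(250L, 750L))
  seg <- data.table::data.table(chrom = "chr1", start = 0L, end = 1000L)
  expect_equal(repeat_content(seg, reps), 0.5)
  inside <- data.table::data.table(chrom = "chr1", start = 100L,
                                   end = 200L)
  expect_equal(repeat_content(inside, reps), 1.0)
  expect_equal(repeat_content(seg, reps[0]), 0)
  # invariance to fragmentation of the repeat annotation
  frag <- data.table::data.table(
    chrom = "chr1", start = c(0L, 100L, 500L, 600L),
    end = c(100L, 250L, 600L, 750L))
  expect_equal(repeat_content(seg, frag), repeat_content(seg, reps))
})

test_that("coverage uniformity reports per-class mean depths", {
  rec <- data.table::data.table(
    chrom = "chr1", start = c(100L, 200L, 1100L, 1200L),
    end = c(101L, 201L, 1101L, 1201L), strand = ".",
    n_mod = 0L, n_valid = c(10L, 10L, 20L, 20L))
  m <- sample_methylome(rec, "t")
  reps <- data.table::data.table(chrom = "chr1", start = 0L, end = 1000L)
  cu <- coverage_uniformity(m, reps)
  expect_equal(cu$mean_depth_repeat, 10)
  expect_equal(cu$mean_depth_nonrepeat, 20)
  expect_equal(cu$abs_difference, 10)
  # empty repeat set: everything is non-repeat
  cu0 <- coverage_uniformity(m, reps[0])
  expect_equal(cu0$mean_depth_nonrepeat, 15)
  expect_true(cu0$flagged)
})

test_that("simulated long-read coverage is uniform across repeats", {
  fx <- small_cohort()
  cu <- coverage_uniformity(fx$sim$methylomes[[1]], fx$ann$repeats)
  depth <- fx$cfg$depth_high
  se <- sqrt(depth / cu$n_repeat) + sqrt(depth / cu$n_nonrepeat)
  expect_lt(cu$abs_difference, 3 * se)
})

test_that("metaplot shows body elevation for planted hyper DMRs", {
  fx <- small_cohort()
  sel <- select_dmrs(viterbi_segment(pool_evidence(fx$cm)), fx$cm)
  hy <- sel$table[selected == TRUE & direction == "hyper"]
  mp <- metaplot(hy, fx$cm)
  body <- mp[mp$zone == "body"]
  flank <- mp[mp$zone != "body"]
  # the groups separate inside the DMR body and converge in the flanks
  body_delta <- mean(body$mean_frac_A - body$mean_frac_B, na.rm = TRUE)
  flank_delta <- mean(flank$mean_frac_A - flank$mean_frac_B, na.rm = TRUE)
  expect_gt(body_delta, 0.3)
  expect_lt(abs(flank_delta), 0.1)
  # flat methylome: flat profile
  flat_cm <- toy_cohort(n_sites = 400L, depth = 30L, seed = 97L)
  seg <- data.table::data.table(chrom = "chr1", start = 1000L, end = 3000L)
  mpf <- metaplot(seg, flat_cm, flank = 500L)
  expect_lt(diff(range(mpf$mean_frac_A, na.rm = TRUE)), 0.35)
  # degenerate binning: single body bin equals the pooled segment score
  mp1 <- suppressWarnings(metaplot(seg, flat_cm, body_bins = 1L))
  ev <- pool_evidence(flat_cm)
  sub <- ev[pos >= 1000 & pos < 3000]
  expect_equal(mp1[mp1$zone == "body"]$mean_frac_A,
               sum(sub$mA) / sum(sub$tA))
})
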